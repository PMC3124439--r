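#' Pearson correlation of profiles to a template, with zero-variance guard
#' @keywords internal
profile_cor <- function(profiles, template) {
  apply(profiles, 1L, function(v) {
    if (stats::sd(v) == 0 || stats::sd(template) == 0) NA_real_
    else stats::cor(v, template)
  })
}

#' Extend a seed group by template matching
#'
#' The template profile is the mean of the seed genes' profiles. The
#' correlation threshold R* is fixed automatically at the largest value that
#' still retrieves every seed gene (i.e. the minimum seed correlation);
#' every gene at or above R* is retrieved.
#'
#' @param profiles Numeric matrix, genes x conditions, rownames = gene ids.
#' @param seed_genes Character vector (>= 2) of gene ids present in
#'   `profiles`.
#' @param mode `"absolute"`: retrieval by |r| >= R* (a profile and its
#'   mirror image both match); `"signed"`: retrieval by r >= R*.
#' @return List with `genes` (retrieved gene ids), `threshold` (chosen R*),
#'   `template` (template profile), and `cor` (named correlation vector).
#'   Constant (zero-variance) profiles are skipped with a warning.
#' @export
extend_by_template <- function(profiles, seed_genes,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  seed_genes <- as.character(seed_genes)
  if (length(seed_genes) < 2L)
    stop("need at least 2 seed genes", call. = FALSE)
  miss <- setdiff(seed_genes, rownames(profiles))
  if (length(miss))
    stop("seed gene(s) absent from profile matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  template <- colMeans(profiles[seed_genes, , drop = FALSE])
  r <- profile_cor(profiles, template)
  if (anyNA(r)) {
    warning(sum(is.na(r)), " constant profile(s) skipped ",
            "(correlation undefined)", call. = FALSE)
  }
  score <- if (mode == "absolute") abs(r) else r
  thr <- min(score[seed_genes], na.rm = TRUE)
  genes <- rownames(profiles)[!is.na(score) & score >= thr]
  list(genes = genes, threshold = thr, template = template, cor = r)
}

#' CAST clustering of expression profiles
#'
#' Clustering Affinity Search Technique with Pearson correlation affinity:
#' a cluster is grown by repeatedly adding the unassigned gene of highest
#' mean correlation to the current members when that affinity is at least
#' `t`, and removing the member of lowest mean affinity when it falls below
#' `t`, until stable; the cluster is then closed and the procedure restarts
#' on the remainder. Tie-breaks: highest affinity first, then lexicographic
#' gene id. Singletons are allowed.
#'
#' @param profiles Numeric matrix, genes x conditions, rownames = gene ids.
#' @param affinity_threshold Correlation threshold t (default 0.8).
#' @return List of character vectors (gene ids), one per cluster, in order
#'   of creation.
#' @export
cast_cluster <- function(profiles, affinity_threshold = 0.8) {
  ids <- rownames(profiles)
  if (is.null(ids)) stop("profiles must have rownames", call. = FALSE)
  if (nrow(profiles) == 1L) return(list(ids))
  sds <- apply(profiles, 1L, stats::sd)
  C <- matrix(0, nrow(profiles), nrow(profiles), dimnames = list(ids, ids))
  ok <- sds > 0
  if (sum(ok) >= 2L)
    C[ok, ok] <- suppressWarnings(stats::cor(t(profiles[ok, , drop = FALSE])))
  C[!ok, ] <- 0; C[, !ok] <- 0
  diag(C) <- 1
  unassigned <- sort(ids)
  clusters <- list()
  t <- affinity_threshold
  while (length(unassigned)) {
    # seed: gene of maximal total affinity to the remaining pool
    tot <- rowSums(C[unassigned, unassigned, drop = FALSE])
    seed <- unassigned[order(-tot, unassigned)][1L]
    members <- seed
    pool <- setdiff(unassigned, seed)
    repeat {
      changed <- FALSE
      repeat {
        if (!length(pool)) break
        aff <- rowMeans(C[pool, members, drop = FALSE])
        best <- order(-aff, pool)[1L]
        if (aff[best] >= t) {
          members <- c(members, pool[best])
          pool <- pool[-best]
          changed <- TRUE
        } else break
      }
      repeat {
        if (length(members) <= 1L) break
        aff <- rowMeans(C[members, members, drop = FALSE])
        worst <- order(aff, members)[1L]
        if (aff[worst] < t) {
          pool <- c(pool, members[worst])
          members <- members[-worst]
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
    unassigned <- sort(pool)
  }
  clusters
}

#' Merge CAST clusters into matching template groups
#'
#' A CAST cluster is absorbed by a template group when the correlation of
#' its mean profile to the group's template meets that group's chosen R*
#' threshold; among several matching groups the best-correlated wins.
#'
#' @param clusters List of gene-id vectors (from [cast_cluster()]).
#' @param profiles Gene x condition matrix covering all cluster genes.
#' @param groups Named list of template-extension results as returned by
#'   [extend_by_template()] (needs `$template` and `$threshold`).
#' @param mode As in [extend_by_template()].
#' @return List with `merged` (named list label -> merged gene ids) and
#'   `novel` (list of unmatched clusters).
#' @export
merge_matching_clusters <- function(clusters, profiles, groups,
                                    mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  merged <- stats::setNames(vector("list", length(groups)), names(groups))
  novel <- list()
  for (cl in clusters) {
    mp <- colMeans(profiles[cl, , drop = FALSE])
    rs <- vapply(groups, function(g) {
      if (stats::sd(mp) == 0 || stats::sd(g$template) == 0) return(NA_real_)
      stats::cor(mp, g$template)
    }, numeric(1))
    score <- if (mode == "absolute") abs(rs) else rs
    thr <- vapply(groups, function(g) g$threshold, numeric(1))
    cand <- which(!is.na(score) & score >= thr)
    if (length(cand)) {
      best <- cand[which.max(score[cand])]
      merged[[best]] <- c(merged[[best]], cl)
    } else {
      novel[[length(novel) + 1L]] <- cl
    }
  }
  list(merged = merged, novel = novel)
}

#' Split a group in two by average-linkage hierarchical clustering
#'
#' Agglomerates the group's profiles on Euclidean distance with average
#' linkage and cuts the tree at the root's two children.
#'
#' @param profiles Gene x condition matrix of the group (>= 2 genes;
#'   singletons are returned unsplit with a warning).
#' @return List of two (or one) character vectors of gene ids.
#' @export
hierarchical_split <- function(profiles) {
  ids <- rownames(profiles)
  if (length(ids) < 2L) {
    warning("group of size ", length(ids), " returned unsplit",
            call. = FALSE)
    return(list(ids))
  }
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  cut <- stats::cutree(hc, k = 2L)
  list(ids[cut == 1L], ids[cut == 2L])
}

#' Full cluster-assignment cascade
#'
#' Seed behaviour groups -> template-matching extension -> CAST on the
#' leftovers -> merging of matching CAST clusters into the template groups
#' -> pooling of the remaining clusters into group X -> per-group
#' average-linkage sub-splitting. Labels A-H are carried by the seed file;
#' X is the heterogeneous remainder.
#'
#' @param profiles Gene x condition matrix of the regulated genes.
#' @param seeds Named list label -> character vector of seed gene ids
#'   (>= 2 each), e.g. as read by [read_seed_file()].
#' @param mode Correlation mode for template matching (see
#'   [extend_by_template()]).
#' @param cast_threshold CAST affinity threshold (default 0.8).
#' @param split Whether to record hierarchical sublabels (default TRUE).
#' @return data.frame `gene_id`, `label`, `stage`
#'   (`template` / `cast` / `cast_novel`), `sublabel`; one row per gene
#'   (a partition of the profile rownames).
#' @export
assign_clusters <- function(profiles, seeds, mode = c("absolute", "signed"),
                            cast_threshold = 0.8, split = TRUE) {
  mode <- match.arg(mode)
  if (is.null(names(seeds)) || any(names(seeds) == ""))
    stop("`seeds` must be a named list (label -> gene ids)", call. = FALSE)
  groups <- lapply(seeds, function(sg)
    extend_by_template(profiles, sg, mode = mode))
  # a gene retrieved by several templates goes to its best-matching one;
  # exact |r| ties resolve toward the signed (positive) match
  label <- stats::setNames(rep(NA_character_, nrow(profiles)),
                           rownames(profiles))
  stage <- label
  best <- stats::setNames(rep(-Inf, nrow(profiles)), rownames(profiles))
  for (lab in names(groups)) {
    g <- groups[[lab]]
    for (gene in g$genes) {
      sc <- if (mode == "absolute") abs(g$cor[gene]) else g$cor[gene]
      sc <- sc + 1e-9 * sign(g$cor[gene])   # signed tie-break
      if (sc > best[gene]) {
        best[gene] <- sc
        label[gene] <- lab
        stage[gene] <- "template"
      }
    }
  }
  # seed genes always stay in their own group
  for (lab in names(seeds)) {
    label[seeds[[lab]]] <- lab
    stage[seeds[[lab]]] <- "template"
  }
  leftover <- names(label)[is.na(label)]
  if (length(leftover)) {
    cl <- cast_cluster(profiles[leftover, , drop = FALSE],
                       affinity_threshold = cast_threshold)
    mg <- merge_matching_clusters(cl, profiles, groups, mode = mode)
    for (lab in names(mg$merged)) {
      for (gene in mg$merged[[lab]]) {
        label[gene] <- lab
        stage[gene] <- "cast"
      }
    }
    for (cl2 in mg$novel) {
      label[cl2] <- "X"
      stage[cl2] <- "cast_novel"
    }
  }
  out <- data.frame(gene_id = names(label), label = unname(label),
                    stage = unname(stage), sublabel = NA_character_,
                    stringsAsFactors = FALSE)
  if (split) {
    for (lab in unique(out$label)) {
      g <- out$gene_id[out$label == lab]
      if (length(g) >= 2L) {
        halves <- hierarchical_split(profiles[g, , drop = FALSE])
        for (k in seq_along(halves))
          out$sublabel[out$gene_id %in% halves[[k]]] <-
            paste0(lab, ".", k)
      } else {
        out$sublabel[out$gene_id %in% g] <- paste0(lab, ".1")
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Read a template seed file
#'
#' TSV with columns `label` and `gene_id`, one seed gene per row.
#'
#' @param path File path.
#' @return Named list label -> character vector of gene ids.
#' @export
read_seed_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "gene_id") %in% names(df)))
    stop("seed file needs columns 'label' and 'gene_id'", call. = FALSE)
  split(df$gene_id, df$label)
}
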