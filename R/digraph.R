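#' Unweighted dominant-direction digraphs from directed GC
#'
#' Two-stage extraction of statistically supported directed connections,
#' designed to tame the multiple-comparisons burden of testing all
#' `R^2 - R` directed entries.  Stage 1: the subjects of one fold are used
#' to run recursive feature elimination on the antisymmetrized dGC
#' (`M - t(M)`) features of the two conditions; the selected features plus
#' their symmetric counterparts form the candidate set K.  Stage 2: for
#' every remaining subject, a phase-scrambling null distribution of dGC is
#' built from that subject's scan, and the K features are tested against it
#' with Bonferroni correction over |K|; a digraph entry is set to 1 for a
#' significant connection whose dGC exceeds the reverse direction (never
#' both directions of one pair).
#'
#' @param gc_list list of `gc_matrices`, one per scan.
#' @param scans matching list of [regional_scan()] objects.
#' @param labels condition label per scan (two conditions).
#' @param subjects subject id per scan.
#' @param stage1_fraction fraction of subjects used for stage-1 RFE.
#' @param alpha significance level (Bonferroni-corrected over |K|).
#' @param n_surr surrogates per subject.
#' @param order VAR order used for surrogate dGC.
#' @param seed RNG seed.
#' @param n1,n2 RFE fold counts for stage 1.
#' @return list with `digraphs` (per stage-2 scan binary matrices),
#'   `K` (candidate feature ids), `stage1` (the `rfe_result`), and the
#'   stage-2 scan index.
#' @export
digraph_pipeline <- function(gc_list, scans, labels, subjects,
                             stage1_fraction = 0.2, alpha = 0.05,
                             n_surr = 100, order = 1, seed = 1,
                             n1 = 5, n2 = 5) {
  set.seed(seed)
  R <- nrow(gc_list[[1]]$dgc)
  anti <- lapply(gc_list, function(g) g$dgc - t(g$dgc))
  us <- unique(subjects)
  s1 <- sample(us, max(2L, ceiling(stage1_fraction * length(us))))
  in1 <- subjects %in% s1
  tab <- feature_table_raw(
    do.call(rbind, lapply(anti[in1], vectorize, which = "dgc")),
    labels = labels[in1], subjects = subjects[in1])
  stage1 <- rfe_two_level(tab, n1 = n1, n2 = n2, seed = seed)
  K <- stage1$selected
  K <- union(K, reverse_edge_ids(K))
  if (length(K) == 0) {
    warning("stage-1 RFE selected no features; digraphs are empty")
  }
  nm <- rownames(gc_list[[1]]$dgc)
  all_ids <- names(vectorize(gc_list[[1]], "dgc"))
  idx2 <- which(!(subjects %in% s1))
  digraphs <- vector("list", length(idx2))
  for (ii in seq_along(idx2)) {
    i <- idx2[ii]
    D <- matrix(0L, R, R, dimnames = dimnames(gc_list[[i]]$dgc))
    if (length(K) > 0) {
      null <- matrix(NA_real_, n_surr, length(all_ids),
                     dimnames = list(NULL, all_ids))
      for (s in seq_len(n_surr)) {
        sur <- apply(scans[[i]]$data, 2, phase_scramble)
        g <- gc_matrices(regional_scan(sur, tr = scans[[i]]$tr),
                         order = order)
        null[s, ] <- vectorize(g, "dgc")
      }
      obs <- vectorize(gc_list[[i]], "dgc")
      thr <- alpha / length(K)
      for (id in K) {
        p <- (1 + sum(null[, id] >= obs[id])) / (n_surr + 1)
        if (p < thr) {
          ij <- edge_id_to_indices(id, nm)
          rev_id <- reverse_edge_ids(id)
          if (obs[id] > obs[rev_id]) D[ij[1], ij[2]] <- 1L
        }
      }
    }
    digraphs[[ii]] <- D
  }
  list(digraphs = digraphs, K = K, stage1 = stage1, stage2_index = idx2)
}

# "a->b" feature ids: swap source and destination
reverse_edge_ids <- function(ids) {
  vapply(strsplit(ids, "->", fixed = TRUE), function(p) {
    paste0(p[2], "->", p[1])
  }, character(1))
}

# destination row, source column of an "src->dst" id
edge_id_to_indices <- function(id, nm) {
  p <- strsplit(id, "->", fixed = TRUE)[[1]]
  c(match(p[2], nm), match(p[1], nm))
}
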