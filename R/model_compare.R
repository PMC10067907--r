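#' Agreement between two clustering models
#'
#' Restricts both labelings to the patients they share, matches the
#' cluster labels of one model to the other by maximising the diagonal
#' of the confusion matrix over all label bijections (exact optimal
#' assignment; reduces to the head-count comparison at k = 2), and
#' reports the fraction of patients on the matched diagonal together
#' with the patients the two models allocate differently.
#'
#' @param labels_a,labels_b named cluster label vectors (names = patient
#'   ids) from the two models.
#' @return List of class `agreement_report`: `n_common`,
#'   `agreement_frac`, `reallocated_ids`, `matching` (named map from
#'   labels of model A to labels of model B).
#' @examples
#' a <- c(p1 = 1, p2 = 1, p3 = 2)
#' b <- c(p1 = 2, p2 = 2, p3 = 1) # same partition, swapped labels
#' cluster_agreement(a, b)$agreement_frac # 1
#' @export
cluster_agreement <- function(labels_a, labels_b) {
  ids <- intersect(names(labels_a), names(labels_b))
  if (length(ids) == 0) stop("the two labelings share no patients")
  a <- as.character(labels_a[ids]); b <- as.character(labels_b[ids])
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  if (k > 7) stop("optimal matching supports at most 7 clusters per model")
  # square confusion matrix, padded with empty labels where the models
  # use different cluster counts
  conf <- matrix(0L, k, k)
  conf[seq_along(la), seq_along(lb)] <- table(factor(a, la), factor(b, lb))
  perms <- perm_matrix(k)
  agree <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(k), p)]))
  best_perm <- perms[which.max(agree), ]
  best <- max(agree)
  row_of <- match(a, la)
  col_of <- match(b, lb)
  on_diag <- best_perm[row_of] == col_of
  real <- best_perm[seq_along(la)] <= length(lb)
  matching <- stats::setNames(lb[best_perm[seq_along(la)][real]],
                              la[real])
  structure(list(n_common = length(ids),
                 agreement_frac = best / length(ids),
                 reallocated_ids = ids[!on_diag],
                 matching = matching),
            class = "agreement_report")
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Cluster model agreement: ",
      format(100 * x$agreement_frac, digits = 3), "% of ",
      x$n_common, " shared patients (", length(x$reallocated_ids),
      " re-allocated)\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' approximately 0 for independent ones.
#'
#' @param labels_a,labels_b cluster label vectors over the same items
#'   (matched by name when both are named).
#' @return The ARI, a number in (-1, 1].
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    ids <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[ids]; labels_b <- labels_b[ids]
  }
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
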