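# Independent brute-force oracles used to cross-check the implementation.

# All-pairs concordance AUC (percent): active scoring strictly better
# counts 1, ties count 0.5.
auc_oracle <- function(scores, labels, lower_is_better = TRUE) {
  x <- if (lower_is_better) -scores else scores
  a <- x[labels]; n <- x[!labels]
  wins <- outer(a, n, ">")
  ties <- outer(a, n, "==")
  100 * (sum(wins) + 0.5 * sum(ties)) / (length(a) * length(n))
}

# Brute-force UPGMA: clusters tracked as leaf index sets; the
# inter-cluster distance is recomputed each step as the plain average of
# all leaf-leaf distances in the original matrix. Ties broken like the
# implementation (lexicographically smallest member label first).
upgma_oracle <- function(d) {
  labels <- rownames(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        li <- min(labels[clusters[[i]]]); lj <- min(labels[clusters[[j]]])
        lo <- sort(c(li, lj))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (lo[1] < best$lo[1] ||
              (lo[1] == best$lo[1] && lo[2] < best$lo[2])))) {
          best <- list(d = dij, i = i, j = j, lo = lo)
        }
      }
    }
    heights <- c(heights, best$d)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- sort(labels[merged])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Recover the oracle-comparable (heights, merged leaf sets) view from an
# upgma_dendrogram.
dendrogram_merge_sets <- function(dend) {
  sets <- list()
  leafset <- function(i) {
    if (i < 0) return(dend$labels[-i])
    sets[[i]]
  }
  for (s in seq_len(nrow(dend$merge))) {
    sets[[s]] <- sort(c(leafset(dend$merge[s, 1]), leafset(dend$merge[s, 2])))
  }
  list(heights = dend$height, merges = sets)
}

# Brute-force rigid-body fit: numerical optimization of RMSD over Euler
# angles and translation.
rmsd_fit_oracle <- function(mobile, reference) {
  rot <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    moved <- t(rot(p[1:3]) %*% t(mobile)) +
      matrix(p[4:6], nrow(mobile), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.2, 1, -1, 1),
                     c(-1, 1, 0.5, 0, 0, 0))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Trapezoidal area under an fpr/tpr curve, fraction scale.
trapz_area <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}
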