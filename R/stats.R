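## Inferential machinery: trial equalization, surrogate nulls, FDR,
## cluster-based permutation, repeated-measures ANOVA, metric group tests.

#' Equalize trial counts between two conditions
#'
#' Randomly subsamples the larger set (without replacement) to the size of
#' the smaller, so signal-to-noise is comparable before any contrast.
#'
#' @param ids_a,ids_b non-empty vectors of trial identifiers.
#' @param seed integer seed.
#' @return list with `a` and `b`, both of length `min(|A|, |B|)`, in their
#'   original order.
#' @export
equalize_trials <- function(ids_a, ids_b, seed = NULL) {
  if (!length(ids_a) || !length(ids_b))
    stop("both trial sets must be non-empty")
  n <- min(length(ids_a), length(ids_b))
  with_seed(seed, {
    a <- if (length(ids_a) > n) sort(sample(seq_along(ids_a), n)) else
      seq_along(ids_a)
    b <- if (length(ids_b) > n) sort(sample(seq_along(ids_b), n)) else
      seq_along(ids_b)
    list(a = ids_a[a], b = ids_b[b])
  })
}

#' Sign-flip Monte Carlo test on per-subject differences
#'
#' The null distribution of the group mean is built by independently
#' negating each subject's difference with probability 0.5 (`n` draws).
#' One-tail p-values use the +1-corrected estimator
#' `(1 + #{null >= obs}) / (n + 1)`; an element is flagged significant when
#' either tail is below `alpha` (default 0.025, i.e. p < 0.025 per tail,
#' two-tailed convention).
#'
#' @param diffs numeric matrix `subjects x elements`; a plain vector is
#'   treated as one subject-per-entry column (a single element).
#' @param n number of random flip patterns (default 20000).
#' @param alpha per-tail significance level (default 0.025).
#' @param seed integer seed.
#' @return list with `observed` (mean per element), `p_lo`, `p_hi`,
#'   `p_two` (= `min(1, 2 * min(p_lo, p_hi))`), and logical `mask`.
#' @export
signflip_monte_carlo <- function(diffs, n = 20000, alpha = 0.025,
                                 seed = NULL) {
  if (is.null(dim(diffs))) diffs <- matrix(diffs, ncol = 1)
  ns <- nrow(diffs)
  if (ns < 2) stop("need at least 2 subjects")
  ne <- ncol(diffs)
  obs <- colMeans(diffs)
  cnt_hi <- numeric(ne); cnt_lo <- numeric(ne)
  with_seed(seed, {
    chunk <- max(1L, floor(2e6 / max(ne, 1)))
    done <- 0L
    while (done < n) {
      m <- min(chunk, n - done)
      flips <- matrix(sample(c(-1, 1), m * ns, replace = TRUE), m, ns)
      null_means <- flips %*% diffs / ns
      cnt_hi <- cnt_hi + colSums(null_means >= rep(obs, each = m))
      cnt_lo <- cnt_lo + colSums(null_means <= rep(obs, each = m))
      done <- done + m
    }
  })
  p_hi <- (1 + cnt_hi) / (n + 1)
  p_lo <- (1 + cnt_lo) / (n + 1)
  list(observed = obs, p_lo = p_lo, p_hi = p_hi,
       p_two = pmin(1, 2 * pmin(p_lo, p_hi)),
       mask = p_lo < alpha | p_hi < alpha)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sort the m p-values ascending, find the largest rank i with
#' `p_(i) <= i q / m`, and reject all hypotheses of rank <= i. Applied
#' separately per analysis time window by the callers.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed, never
#'   rejected).
#' @param q target false-discovery rate.
#' @return logical rejection mask, same length as `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  mask <- rep(FALSE, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(mask)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  below <- pv[o] <= seq_len(m) * q / m
  if (any(below)) {
    k <- max(which(below))
    mask[ok[o[seq_len(k)]]] <- TRUE
  }
  mask
}

## clusters of contiguous suprathreshold t-values within one band;
## positive and negative excursions form separate clusters
band_clusters <- function(tv, t_crit) {
  cat_ <- ifelse(tv > t_crit, 1L, ifelse(tv < -t_crit, -1L, 0L))
  r <- rle(cat_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    list(start = starts[k], end = ends[k], sign = r$values[k],
         t_sum = sum(tv[idx]))
  })
}

max_cluster_stat <- function(tmat, t_crit) {
  mx <- 0
  for (b in seq_len(nrow(tmat))) {
    cl <- band_clusters(tmat[b, ], t_crit)
    if (length(cl))
      mx <- max(mx, max(vapply(cl, function(c) abs(c$t_sum), numeric(1))))
  }
  mx
}

## paired t maps for a set of sign-flip patterns, fully vectorized:
## D is subjects x elements, flips is n_perm x subjects (+-1)
flip_t_maps <- function(D, flips) {
  ns <- nrow(D)
  M <- flips %*% D / ns
  ms <- rep(colMeans(D^2), each = nrow(flips))
  v <- (ms - M^2) * ns / (ns - 1)
  M / sqrt(pmax(v, .Machine$double.eps) / ns)
}

#' Cluster-based permutation test on paired condition maps
#'
#' Per (band, time) element a paired t statistic is computed across animals;
#' elements beyond the t threshold (paired t, `t_alpha` two-tailed) are
#' clustered by temporal adjacency within band (positive and negative
#' excursions separately; no frequency adjacency). The cluster statistic is
#' the sum of t values. The null distribution is the maximum |t-sum| over
#' `n_perm` within-animal condition-label permutations (equivalently random
#' sign flips of the per-animal difference maps); cluster p-values use the
#' +1-corrected Monte Carlo estimator and are significant at
#' `cluster_alpha` (default 0.05).
#'
#' @param maps_a,maps_b numeric arrays `animal x band x time` (paired).
#' @param t_alpha two-tailed alpha defining the clustering t threshold
#'   (default 0.025).
#' @param n_perm number of permutations (default 1000).
#' @param cluster_alpha cluster-level significance (default 0.05).
#' @param seed integer seed.
#' @return list of class `cluster_result`: `clusters` (data.frame band,
#'   start, end, sign, t_sum, p, significant), `t_map`, `t_crit`, `null`
#'   (max |t-sum| distribution), `n_perm`.
#' @export
cluster_permutation <- function(maps_a, maps_b, t_alpha = 0.025,
                                n_perm = 1000, cluster_alpha = 0.05,
                                seed = NULL) {
  stopifnot(all(dim(maps_a) == dim(maps_b)), length(dim(maps_a)) == 3)
  na <- dim(maps_a)[1]; nb <- dim(maps_a)[2]; nt <- dim(maps_a)[3]
  if (na < 2) stop("need at least 2 animals")
  D <- maps_a - maps_b
  Dm <- matrix(D, nrow = na)                  # animals x (band*time)
  t_obs <- flip_t_maps(Dm, matrix(1, 1, na))
  tmat <- matrix(t_obs, nb, nt)
  t_crit <- stats::qt(1 - t_alpha / 2, df = na - 1)

  cl_list <- list()
  for (b in seq_len(nb)) {
    cls <- band_clusters(tmat[b, ], t_crit)
    for (cl in cls)
      cl_list[[length(cl_list) + 1]] <- data.frame(
        band = b, start = cl$start, end = cl$end, sign = cl$sign,
        t_sum = cl$t_sum)
  }
  null <- numeric(n_perm)
  with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * na, replace = TRUE),
                    n_perm, na)
    tperm <- flip_t_maps(Dm, flips)
    for (i in seq_len(n_perm))
      null[i] <- max_cluster_stat(matrix(tperm[i, ], nb, nt), t_crit)
  })
  clusters <- if (length(cl_list)) do.call(rbind, cl_list) else
    data.frame(band = integer(), start = integer(), end = integer(),
               sign = integer(), t_sum = numeric())
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$t_sum, function(s)
      (1 + sum(null >= abs(s))) / (1 + n_perm), numeric(1))
    clusters$significant <- clusters$p < cluster_alpha
  } else {
    clusters$p <- numeric(); clusters$significant <- logical()
  }
  structure(list(clusters = clusters, t_map = tmat, t_crit = t_crit,
                 null = null, n_perm = n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), t_crit = ",
      signif(x$t_crit, 4), ", ", sum(x$clusters$significant),
      " significant at the cluster level\n", sep = "")
  invisible(x)
}

#' Two-way repeated-measures ANOVA on region-of-interest values
#'
#' Fully-within-subject two-factor design (animal as the repeated factor):
#' each effect is tested against its own interaction-with-subject error
#' term. No sphericity correction is applied (noted in the output).
#'
#' @param values numeric array `animal x levelsA x levelsB`, complete (no
#'   `NA`: missing cells are an error, there is no imputation).
#' @param factor_names names of the two factors.
#' @param alpha significance level (default 0.025).
#' @return data.frame with `effect`, `df1`, `df2`, `ss`, `F`, `p`,
#'   `significant`; attribute `sphericity_correction = "none"`.
#' @export
rm_anova_roi <- function(values, factor_names = c("A", "B"), alpha = 0.025) {
  stopifnot(length(dim(values)) == 3)
  if (anyNA(values)) stop("missing cells are not allowed (no imputation)")
  n <- dim(values)[1]; a <- dim(values)[2]; b <- dim(values)[3]
  stopifnot(n >= 2, a >= 2, b >= 2)
  grand <- mean(values)
  m_s <- apply(values, 1, mean)
  m_a <- apply(values, 2, mean)
  m_b <- apply(values, 3, mean)
  m_sa <- apply(values, c(1, 2), mean)
  m_sb <- apply(values, c(1, 3), mean)
  m_ab <- apply(values, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb

  mk <- function(effect, ss, df1, ss_err, df2) {
    ms_err <- ss_err / df2
    F <- if (ms_err > 0) (ss / df1) / ms_err else
      (if (ss > 0) Inf else 0)
    data.frame(effect = effect, df1 = df1, df2 = df2, ss = ss, F = F,
               p = stats::pf(F, df1, df2, lower.tail = FALSE))
  }
  out <- rbind(
    mk(factor_names[1], ss_a, a - 1, ss_sa, (n - 1) * (a - 1)),
    mk(factor_names[2], ss_b, b - 1, ss_sb, (n - 1) * (b - 1)),
    mk(paste(factor_names, collapse = ":"), ss_ab, (a - 1) * (b - 1),
       ss_sab, (n - 1) * (a - 1) * (b - 1)))
  out$significant <- out$p < alpha
  attr(out, "sphericity_correction") <- "none"
  out
}

#' Group test for phase-amplitude coupling matrices
#'
#' One-sample t test on (post - pre) PAC per matrix cell across
#' subject-session observations, Benjamini-Hochberg corrected across cells.
#' Cells with fewer than 3 observations are skipped (`NA`).
#'
#' @param pac_post,pac_pre numeric matrices `observations x cells` (flatten
#'   a `pac_matrix` array per observation; `NA` cells allowed).
#' @param q FDR level (default 0.05).
#' @return list with `t`, `p`, `mask` (BH-FDR rejection), `mean_diff`, `n`.
#' @export
pac_group_test <- function(pac_post, pac_pre, q = 0.05) {
  stopifnot(all(dim(pac_post) == dim(pac_pre)))
  d <- pac_post - pac_pre
  nc <- ncol(d)
  tv <- pv <- md <- rep(NA_real_, nc)
  nn <- integer(nc)
  for (j in seq_len(nc)) {
    x <- d[, j]; x <- x[!is.na(x)]
    nn[j] <- length(x)
    if (length(x) < 3) next
    md[j] <- mean(x)
    s <- stats::sd(x)
    if (s == 0) { tv[j] <- if (md[j] == 0) 0 else Inf * sign(md[j]) }
    else tv[j] <- md[j] / (s / sqrt(length(x)))
    pv[j] <- 2 * stats::pt(abs(tv[j]), df = length(x) - 1,
                           lower.tail = FALSE)
  }
  list(t = tv, p = pv, mask = bh_fdr(pv, q), mean_diff = md, n = nn)
}

#' Trial-shuffle significance test for differential phase TE
#'
#' Per band, surrogate dTE values are computed with the trial pairing
#' between the two channels permuted (uniform random permutations of one
#' channel's trial order, redrawn when the identity comes up; cyclic
#' rotations alone would give only `n_trials - 1` distinct surrogates, far
#' too coarse a null at realistic trial counts); the two-sided Monte Carlo
#' p-value uses the +1-corrected estimator on |dTE|, and significance is
#' Benjamini-Hochberg corrected across bands.
#'
#' @param dte a [dte_spectrum()] result (carries the trial phases).
#' @param n_shuffles number of surrogates (default 1000).
#' @param q FDR level (default 0.05).
#' @param seed integer seed.
#' @return data.frame with `freq`, `dte`, `p`, `significant`; attribute
#'   `null` holds the per-band surrogate matrices.
#' @export
pte_shuffle_test <- function(dte, n_shuffles = 1000, q = 0.05, seed = NULL) {
  phases <- attr(dte, "phases")
  n_bins <- attr(dte, "n_bins")
  if (is.null(phases)) stop("dte must come from dte_spectrum()")
  nb <- nrow(dte)
  null <- matrix(NA_real_, n_shuffles, nb)
  with_seed(seed, {
    for (b in seq_len(nb)) {
      ph <- phases[[b]]
      ntr <- nrow(ph$x)
      if (ntr < 2) stop("trial-shuffle surrogates need at least 2 trials")
      bx <- phase_bin(ph$x, n_bins)
      by <- phase_bin(ph$y, n_bins)
      for (s in seq_len(n_shuffles)) {
        repeat {
          perm <- sample.int(ntr)
          if (!all(perm == seq_len(ntr))) break
        }
        null[s, b] <- te_binned(bx, by[perm, , drop = FALSE], ph$delay,
                                n_bins) -
          te_binned(by[perm, , drop = FALSE], bx, ph$delay, n_bins)
      }
    }
  })
  p <- vapply(seq_len(nb), function(b)
    (1 + sum(abs(null[, b]) >= abs(dte$dte[b]))) / (1 + n_shuffles),
    numeric(1))
  out <- data.frame(freq = dte$freq, dte = dte$dte, p = p,
                    significant = bh_fdr(p, q))
  attr(out, "null") <- null
  out
}
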