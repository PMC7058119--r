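## Solution space of the subclonal-frequency equation set --------------------
##
## A segment observed with average copy number Cbar and folded average BAF
## mu_hat constrains the triple (phi, C, mu_T) through
##     Cbar = phi*C + (1 - phi)*2
##     Cbar = [phi*C*mu_T + (1 - phi)] / mu_bar
## Different integer copy numbers C can explain the same observation whenever
## their (C, mu_hat^T) pairs share the invariant
##     xi = (C*mu_hat^T - 1) / (C - 2),
## so the observations reachable by several solutions lie on a family of
## curves indexed by xi.  This file enumerates that family exactly (rational
## arithmetic) and classifies the solution count of a given observation.

#' Subclonal frequency from an average copy number
#'
#' Solves `cbar = phi*C + (1 - phi)*2` for `phi`.  The caller is responsible
#' for checking membership of the result in \[0, 1\].
#'
#' @param cbar positive average copy number.
#' @param C integer absolute copy number, `C != 2`.
#' @return `(cbar - 2) / (C - 2)`.
#' @export
phi_from_avg_copy <- function(cbar, C) {
  if (any(C == 2)) {
    stop("C = 2 leaves phi undetermined (any phi gives cbar = 2)")
  }
  (cbar - 2) / (C - 2)
}

#' The xi invariant of a (copy number, folded tumor BAF) pair
#'
#' @param C integer absolute copy number, `C != 2`.
#' @param mu_hat folded tumor BAF in \[0, 0.5\].
#' @return `(C * mu_hat - 1) / (C - 2)`.
#' @export
xi_value <- function(C, mu_hat) {
  if (any(C == 2)) stop("xi is undefined at C = 2")
  (C * mu_hat - 1) / (C - 2)
}

rational_key <- function(num, den) {
  # reduced-fraction key with positive denominator
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  if (num == 0) return("0/1")
  g <- gcd_int(abs(num), den)
  paste0(num %/% g, "/", den %/% g)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Enumerate the xi-curve family
#'
#' Enumerates all genotype-realizable pairs `(C, mu_hat = m/C)` where `m =
#' min(#M, #P)` ranges over `0..floor(C/2)`, for copy numbers `C` from 3 to
#' `c_max` (the neutral `C = 2` is excluded by the definition of xi), groups
#' them by exact rational xi, and returns the distinct curves sorted by xi.
#' Pure deletions (`C` 0 and 1) carry no heterozygous B-allele curve and are
#' excluded by default; `include_deletions = TRUE` adds `C = 1` (`mu_hat` 0).
#'
#' @param c_max maximum absolute copy number (>= 3).
#' @param include_deletions include the single-copy deletion state.
#' @return data.frame with one row per curve: `xi`, `xi_num`, `xi_den`,
#'   `n_members`, `multi_solution`, and a `members` list column of
#'   data.frames `(C, m, mu_hat)`.
#' @export
enumerate_curves <- function(c_max = 15, include_deletions = FALSE) {
  stopifnot(c_max >= 3)
  cs <- 3:c_max
  if (include_deletions) cs <- c(1L, cs)
  members <- do.call(rbind, lapply(cs, function(C) {
    m <- 0:(C %/% 2)
    data.frame(C = C, m = m, mu_hat = m / C)
  }))
  # xi = (m - 1)/(C - 2) exactly
  key <- mapply(rational_key, members$m - 1, members$C - 2)
  groups <- split(members, key)
  xi <- vapply(groups, function(g) (g$m[1] - 1) / (g$C[1] - 2), 0)
  ord <- order(xi)
  groups <- groups[ord]
  xi <- xi[ord]
  frac <- strsplit(names(groups), "/", fixed = TRUE)
  out <- data.frame(
    xi = xi,
    xi_num = vapply(frac, function(f) as.integer(f[1]), 0L),
    xi_den = vapply(frac, function(f) as.integer(f[2]), 0L),
    n_members = vapply(groups, nrow, 0L),
    row.names = NULL)
  out$multi_solution <- vapply(groups, curve_is_multi_solution, FALSE)
  out$members <- lapply(groups, function(g) {
    rownames(g) <- NULL
    g[order(g$C), , drop = FALSE]
  })
  out
}

curve_is_multi_solution <- function(members) {
  # brute force over member pairs: a curve presents multiple phi solutions
  # when two members (C', mu'), (C'', mu'') both solve the equation set for
  # some admissible observation with cbar in (2, min(C', C''))
  members <- members[members$C >= 3, , drop = FALSE]
  if (nrow(members) < 2) return(FALSE)
  for (i in seq_len(nrow(members) - 1)) {
    for (j in (i + 1):nrow(members)) {
      c1 <- members$C[i]; mu1 <- members$mu_hat[i]
      c2 <- members$C[j]; mu2 <- members$mu_hat[j]
      hi <- min(c1, c2)
      if (hi <= 2) next
      for (cbar in seq(2, hi, length.out = 9)[c(-1, -9)]) {
        phi1 <- phi_from_avg_copy(cbar, c1)
        phi2 <- phi_from_avg_copy(cbar, c2)
        if (phi1 < 0 || phi1 > 1 || phi2 < 0 || phi2 > 1) next
        b1 <- folded_mean_baf(phi1, c1, mu1, cbar)
        b2 <- folded_mean_baf(phi2, c2, mu2, cbar)
        if (abs(b1 - b2) < 1e-12 && abs(phi1 - phi2) > 1e-9) return(TRUE)
      }
    }
  }
  FALSE
}

folded_mean_baf <- function(phi, C, mu_t, cbar) {
  mu_bar <- (phi * C * mu_t + (1 - phi)) / cbar
  min(mu_bar, 1 - mu_bar)
}

#' Count the multi-solution curves of the xi family
#'
#' @inheritParams enumerate_curves
#' @return integer: number of curves on which some admissible observation
#'   admits at least two distinct subclonal-frequency solutions under the
#'   `c_max` restriction.
#' @export
count_multi_solution_curves <- function(c_max = 15, include_deletions = FALSE) {
  sum(enumerate_curves(c_max, include_deletions)$multi_solution)
}

#' Classify the solutions of the subclonal-frequency equations
#'
#' Given an observed average copy number `cbar` and folded average BAF(s),
#' enumerates every `(phi, C, mu_T)` triple with `C <= c_max` that satisfies
#' the equation set, and reports the case of the solution-count analysis that
#' applies: a unique solution when `cbar < 2`, or when `cbar > 2` but
#' `cbar < 1/mu_hat`; multiple solutions (infinitely many without the
#' `c_max` restriction) when `cbar > 2` and `cbar >= 1/mu_hat`.
#'
#' @param cbar positive observed average copy number.
#' @param baf_hats folded average BAF observation(s) in \[0, 0.5\].
#' @param c_max maximum absolute copy number (>= 3).
#' @param tol matching tolerance for the BAF equation and the \[0,1\] bounds
#'   on phi.
#' @param restrict_cmax if `FALSE`, the `count_class` reports `"infinite"`
#'   whenever the unrestricted infinite case applies (the solution list is
#'   still the finite `c_max`-restricted enumeration).
#' @return list with `count_class` (`"unique"`, `"multiple"` or
#'   `"infinite"`), `infinite_without_cmax` (logical), and `solutions`, a
#'   data.frame `(phi, C, n_m, mu_t, xi)` sorted by `phi`.
#' @export
classify_solutions <- function(cbar, baf_hats, c_max = 15, tol = 1e-6,
                               restrict_cmax = TRUE) {
  stopifnot(c_max >= 3, cbar > 0)
  if (any(baf_hats < -tol | baf_hats > 0.5 + tol)) {
    stop("folded BAF outside [0, 0.5]")
  }
  obs <- mean(baf_hats)
  if (abs(cbar - 2) <= tol) {
    sol <- data.frame(phi = 0, C = 2L, n_m = 1L, mu_t = 0.5,
                      xi = NA_real_)
    return(list(count_class = "unique", infinite_without_cmax = FALSE,
                solutions = sol))
  }
  sols <- list()
  for (C in setdiff(0:c_max, 2L)) {
    phi <- phi_from_avg_copy(cbar, C)
    if (phi < -tol || phi > 1 + tol) next
    phi <- min(max(phi, 0), 1)
    if (C == 0) {
      # no B allele in the tumor genotype: folded BAF is 0.5 from the
      # normal-cell contribution alone
      if (max(abs(baf_hats - 0.5)) <= tol) {
        sols[[length(sols) + 1]] <- data.frame(
          phi = phi, C = 0L, n_m = 0L, mu_t = NA_real_,
          xi = xi_value(0L, 0))
      }
      next
    }
    for (m in 0:(C %/% 2)) {
      mu_t <- m / C
      expected <- folded_mean_baf(phi, C, mu_t, cbar)
      if (max(abs(baf_hats - expected)) <= tol) {
        sols[[length(sols) + 1]] <- data.frame(
          phi = phi, C = as.integer(C), n_m = as.integer(m), mu_t = mu_t,
          xi = xi_value(C, mu_t))
      }
    }
  }
  solutions <- if (length(sols) > 0) do.call(rbind, sols) else
    data.frame(phi = numeric(), C = integer(), n_m = integer(),
               mu_t = numeric(), xi = numeric())
  solutions <- solutions[order(solutions$phi, solutions$C), , drop = FALSE]
  rownames(solutions) <- NULL
  n_phi <- length(unique(round(solutions$phi / tol) * tol))
  infinite <- cbar > 2 && obs > 0 && cbar >= 1 / obs - tol
  count_class <- if (cbar < 2) "unique"
    else if (!restrict_cmax && infinite) "infinite"
    else if (n_phi > 1) "multiple" else "unique"
  list(count_class = count_class, infinite_without_cmax = infinite,
       solutions = solutions)
}
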