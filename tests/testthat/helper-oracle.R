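# Independent brute-force oracle for the subclonal-frequency equation set:
# for every copy number C and minority count m, solve the average-copy
# equation for phi numerically (uniroot on the residual, not the algebraic
# inversion used by the package) and keep the (phi, C, m) triples whose
# expected folded BAF matches the observation.

oracle_solutions <- function(cbar, muhat, c_max, tol = 1e-6) {
  out <- list()
  for (C in setdiff(0:c_max, 2L)) {
    for (m in 0:(C %/% 2)) {
      f <- function(phi) phi * C + (1 - phi) * 2 - cbar
      if (abs(f(0)) < 1e-12) {
        phi <- 0
      } else if (sign(f(0)) == sign(f(1))) {
        next
      } else {
        phi <- stats::uniroot(f, c(0, 1), tol = 1e-13)$root
      }
      baf <- if (C == 0) 0.5 else {
        mu <- (phi * m + (1 - phi)) / cbar
        min(mu, 1 - mu)
      }
      if (abs(baf - muhat) <= tol) {
        out[[length(out) + 1]] <- data.frame(phi = phi, C = C, m = m)
      }
      if (C == 0) break
    }
  }
  if (length(out) == 0) {
    return(data.frame(phi = numeric(), C = integer(), m = integer()))
  }
  do.call(rbind, out)
}

distinct_phis <- function(phi, tol = 1e-6) {
  phi <- sort(phi)
  if (length(phi) == 0) return(numeric())
  phi[c(TRUE, diff(phi) > tol)]
}

# random observation generated from a true (phi, C, genotype) triple
random_solvable_case <- function(c_max) {
  repeat {
    C <- sample(setdiff(0:c_max, 2L), 1)
    m <- sample(0:max(0, C %/% 2), 1)
    phi <- round(runif(1, 0.02, 0.98), 4)
    cbar <- phi * C + (1 - phi) * 2
    if (abs(cbar - 2) < 0.01) next
    muhat <- if (C == 0) 0.5 else {
      mu <- (phi * m + (1 - phi)) / cbar
      min(mu, 1 - mu)
    }
    return(list(phi = phi, C = C, m = m, cbar = cbar, muhat = muhat))
  }
}
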