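## GC-bias correction of the tumor/normal read-count ratio -------------------
##
## The tumor/normal read-count ratio (RCR) of NGS data shows a log-linear
## dependence on segment GC content.  The model here is a single line in log
## space, log(RCR) = slope * gc + intercept, anchored at a reference GC so
## that the forward (correct) and inverse transforms are exact algebraic
## inverses of each other: the inverse is what the Poisson read-count
## likelihood needs to map an expected corrected ratio back to raw scale.

#' Construct a GC-bias model
#'
#' @param slope change in log read-count ratio per unit GC fraction.
#' @param intercept intercept of the log-linear fit (kept for serialization;
#'   the correction itself only uses `slope` and `reference_gc`).
#' @param reference_gc GC fraction at which the correction is anchored;
#'   segments at this GC are left untouched.
#' @return an object of class `bias_model`.
#' @export
bias_model <- function(slope = 0, intercept = 0, reference_gc = 0.5) {
  stopifnot(is.finite(slope), is.finite(intercept),
            reference_gc >= 0, reference_gc <= 1)
  structure(list(slope = slope, intercept = intercept,
                 reference_gc = reference_gc),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> slope ", format(x$slope, digits = 4),
      ", intercept ", format(x$intercept, digits = 4),
      ", reference gc ", format(x$reference_gc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fit the log-linear GC-bias model to a segment set
#'
#' Least-squares fit of `log(tumor_reads / normal_reads)` against GC
#' fraction over all segments, made robust by iterated 3-MAD trimming of
#' residuals: segments carrying copy-number changes are ratio outliers that
#' would otherwise leak into the slope, and the trim-refit loop (to a stable
#' kept set, at most 10 passes) converges onto the copy-neutral majority.
#' The anchor `reference_gc` is the length-weighted mean GC.
#'
#' @param segset a [segment_set] with positive read counts.
#' @return a [bias_model].
#' @export
fit_bias <- function(segset) {
  seg <- segset$segments
  keep <- seg$tumor_reads > 0 & seg$normal_reads > 0
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) < 2) stop("need at least 2 segments with positive counts to fit bias")
  y <- log(seg$tumor_reads / seg$normal_reads)
  gc <- seg$gc
  len <- seg$end - seg$start
  ref_gc <- sum(gc * len) / sum(len)
  if (length(unique(gc)) < 2) {
    warning("all segments share one GC value; returning a zero-slope bias model")
    return(bias_model(0, mean(y), ref_gc))
  }
  kept <- rep(TRUE, length(y))
  fit <- stats::lm.fit(cbind(1, gc), y)
  for (pass in 1:10) {
    res <- y - drop(cbind(1, gc) %*% fit$coefficients)
    mad_res <- stats::mad(res[kept])
    if (mad_res == 0) break
    new_kept <- abs(res - stats::median(res[kept])) <= 3 * mad_res
    if (sum(new_kept) < 2 || length(unique(gc[new_kept])) < 2) break
    if (identical(new_kept, kept)) break
    kept <- new_kept
    fit <- stats::lm.fit(cbind(1, gc[kept]), y[kept])
  }
  bias_model(slope = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]),
             reference_gc = ref_gc)
}

check_gc <- function(gc) {
  if (any(gc < 0 | gc > 1)) stop("gc fraction outside [0, 1]")
  gc
}

#' Correct a raw read-count ratio for GC bias
#'
#' Returns `exp(log(raw_ratio) - slope * (gc - reference_gc))`.  After
#' correction, segments with equal average copy number share a common
#' expected ratio regardless of their GC content.
#'
#' @param model a [bias_model].
#' @param raw_ratio positive raw tumor/normal read-count ratio (vectorized).
#' @param gc GC fraction in \[0,1\] (vectorized).
#' @return corrected ratio(s).
#' @seealso [bias_invert()] for the exact inverse.
#' @export
bias_correct <- function(model, raw_ratio, gc) {
  if (any(raw_ratio <= 0)) stop("raw_ratio must be positive")
  check_gc(gc)
  exp(log(raw_ratio) - model$slope * (gc - model$reference_gc))
}

#' Invert the GC-bias correction
#'
#' Exact inverse of [bias_correct()]:
#' `bias_invert(m, bias_correct(m, r, g), g)` equals `r` to floating
#' tolerance.  Used to map an expected corrected ratio back to the raw scale
#' of the observed read counts.
#'
#' @inheritParams bias_correct
#' @param corrected_ratio positive corrected ratio (vectorized).
#' @return raw-scale ratio(s).
#' @export
bias_invert <- function(model, corrected_ratio, gc) {
  if (any(corrected_ratio <= 0)) stop("corrected_ratio must be positive")
  check_gc(gc)
  exp(log(corrected_ratio) + model$slope * (gc - model$reference_gc))
}

#' Apply GC-bias correction to every segment of a set
#'
#' Fills the `corrected_ratio` column with
#' `bias_correct(model, tumor_reads / normal_reads, gc)`.
#'
#' @param segset a [segment_set].
#' @param model a [bias_model]; the default identity model copies the raw
#'   ratio through unchanged.
#' @return the segment set with `corrected_ratio` set.
#' @export
apply_bias_correction <- function(segset, model = bias_model()) {
  seg <- segset$segments
  if (any(seg$tumor_reads <= 0)) {
    # fully deleted segments can have zero tumor reads; floor at one read to
    # keep the ratio positive (the Poisson likelihood still sees the raw count)
    ratio <- pmax(seg$tumor_reads, 1) / seg$normal_reads
  } else {
    ratio <- seg$tumor_reads / seg$normal_reads
  }
  segset$segments$corrected_ratio <- bias_correct(model, ratio, seg$gc)
  segset
}

#' Serialize / deserialize a bias model
#'
#' @param model a [bias_model].
#' @param path YAML file path.
#' @return `write_bias_model` returns `path` invisibly; `read_bias_model`
#'   returns a [bias_model].
#' @export
write_bias_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_bias_model
#' @export
read_bias_model <- function(path) {
  x <- yaml::read_yaml(path)
  bias_model(x$slope, x$intercept, x$reference_gc)
}
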