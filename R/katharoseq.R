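#' Read a titration-control table
#'
#' TSV with columns `control_id`, `total_reads`, `fraction_correct`: one row
#' per extraction-positive control, giving its sequencing read total and the
#' fraction of reads assigned to the expected control taxa.
#'
#' @param path path to a TSV file.
#' @return data.frame with the three columns above.
#' @export
read_titration_controls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("control_id", "total_reads", "fraction_correct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("controls file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

.lod_sigmoid <- function(x, f0, f1, m, h) f0 + (f1 - f0) / (1 + (m / x)^h)

#' Fit a limit-of-detection titration curve
#'
#' Dilution series of extraction-positive controls trace out how the
#' fraction of reads mapping to the expected control taxa rises with read
#' depth. The curve is modelled as a four-parameter Hill sigmoid on
#' log10 read count, f(x) = f0 + (f1 - f0) / (1 + (m/x)^h) with
#' x = log10(total_reads): floor `f0`, ceiling `f1`, midpoint `m` (log10
#' reads) and slope `h > 0`. If the least-squares fit does not converge, or
#' the points are degenerate (no spread in fraction_correct), the curve
#' falls back to monotone linear interpolation of the empirical points and
#' is flagged as such.
#'
#' @param controls data.frame with columns `total_reads` (positive integers)
#'   and `fraction_correct` (in \[0, 1\]); at least 4 points spanning one
#'   order of magnitude in reads.
#' @return an object of class `lod_curve`: the points, the fitted
#'   parameters (`f0`, `f1`, `m`, `h`), the residual sum of squares, and
#'   `method` (`"sigmoid"` or `"interpolation"`).
#' @export
fit_lod_curve <- function(controls) {
  reads <- controls$total_reads
  frac <- controls$fraction_correct
  if (length(reads) < 4)
    stop("need at least 4 control points to fit a titration curve")
  if (any(reads <= 0) || any(reads != floor(reads)))
    stop("total_reads must be positive integers")
  if (any(frac < 0 | frac > 1))
    stop(sprintf("fraction_correct %g outside [0, 1]", frac[which(frac < 0 | frac > 1)[1L]]))
  if (log10(max(reads) / min(reads)) < 1)
    stop("control read counts must span at least one order of magnitude")
  x <- log10(reads)
  out <- list(points = data.frame(total_reads = reads, fraction_correct = frac),
              f0 = NA_real_, f1 = NA_real_, m = NA_real_, h = NA_real_,
              rss = NA_real_, method = "interpolation")
  degenerate <- diff(range(frac)) < 1e-8
  if (!degenerate) {
    start <- c(f0 = max(min(frac), 1e-3), f1 = min(max(frac), 1),
               m = x[which.min(abs(frac - (min(frac) + max(frac)) / 2))],
               h = 4)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) frac - .lod_sigmoid(x, p[1], p[2],
                                                              p[3], p[4]),
                         lower = c(0, 0, 1e-6, 1e-6),
                         upper = c(1, 1, 12, 100),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      p <- as.list(fit$par)
      if (p$f0 <= p$f1 && p$h > 0) {
        out[c("f0", "f1", "m", "h")] <- p[c("f0", "f1", "m", "h")]
        out$rss <- sum(fit$fvec^2)
        out$method <- "sigmoid"
      }
    }
  }
  structure(out, class = "lod_curve")
}

#' @export
print.lod_curve <- function(x, ...) {
  cat("Limit-of-detection titration curve (", nrow(x$points), " controls)\n",
      sep = "")
  if (x$method == "sigmoid") {
    cat(sprintf("  sigmoid fit: f0 = %.4g, f1 = %.4g, m = %.4g (log10 reads), h = %.4g\n",
                x$f0, x$f1, x$m, x$h))
    cat(sprintf("  residual sum of squares: %.4g\n", x$rss))
  } else {
    cat("  fallback: monotone interpolation of empirical points\n")
  }
  invisible(x)
}

# monotone empirical curve: fraction as a non-decreasing step/linear
# interpolation of the observed points on log10 reads
.lod_empirical <- function(curve) {
  pts <- curve$points[order(curve$points$total_reads), ]
  x <- log10(pts$total_reads)
  y <- cummax(pts$fraction_correct)
  agg <- tapply(y, x, max)
  list(x = as.numeric(names(agg)), y = as.numeric(agg))
}

#' Read-count exclusion threshold from a titration curve
#'
#' The smallest integer read count at which the fitted curve reaches the
#' target fraction of correctly assigned reads. Rounding is upward, so the
#' guarantee is conservative: every sample at or above the returned depth is
#' expected to read out at least `target_fraction` correctly.
#'
#' @param curve an [fit_lod_curve()] result.
#' @param target_fraction required fraction of correctly assigned reads
#'   (default 0.9).
#' @return positive integer read count.
#' @export
exclusion_threshold <- function(curve, target_fraction = 0.9) {
  stopifnot(inherits(curve, "lod_curve"))
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  t <- target_fraction
  if (curve$method == "sigmoid") {
    if (curve$f1 < t)
      stop(sprintf("controls never reach target fraction: ceiling %.4g < %.4g",
                   curve$f1, t))
    if (t <= curve$f0 + 1e-12) return(1L)
    ratio <- (curve$f1 - t) / (t - curve$f0)
    # at the ceiling the analytic crossing is at infinity; accept attainment
    # within machine tolerance instead
    if (ratio < 1e-9)
      ratio <- (curve$f1 - t + 1e-9) / (t - curve$f0)
    xstar <- curve$m / ratio^(1 / curve$h)
    if (10^xstar >= .Machine$integer.max)
      stop("target fraction is attained only beyond representable read depths")
    r <- as.integer(ceiling(10^xstar - 1e-9))
    if (.lod_sigmoid(log10(r), curve$f0, curve$f1, curve$m, curve$h) < t - 1e-12)
      r <- r + 1L
    return(max(r, 1L))
  }
  emp <- .lod_empirical(curve)
  if (max(emp$y) < t)
    stop(sprintf("controls never reach target fraction: max %.4g < %.4g",
                 max(emp$y), t))
  if (emp$y[1L] >= t) return(as.integer(ceiling(10^emp$x[1L] - 1e-9)))
  i <- which(emp$y >= t)[1L]
  # linear crossing within the segment [i-1, i] on the log10-read axis
  x0 <- emp$x[i - 1L]; x1 <- emp$x[i]
  y0 <- emp$y[i - 1L]; y1 <- emp$y[i]
  xstar <- if (y1 > y0) x0 + (t - y0) * (x1 - x0) / (y1 - y0) else x1
  as.integer(ceiling(10^xstar - 1e-9))
}

#' Rarefy a feature table to fixed depth
#'
#' Each retained sample's counts are replaced by a uniform random subsample
#' of its reads drawn WITHOUT replacement (classical rarefaction: per-feature
#' counts are jointly multivariate hypergeometric), summing exactly to
#' `depth`. Samples whose total falls below `depth` are dropped and reported,
#' never padded. The draw is deterministic given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param table a [feature_table()].
#' @param depth positive integer rarefaction depth.
#' @param seed integer seed for the subsampling RNG.
#' @return list with `table` (rarefied [feature_table()]),
#'   `dropped_samples` (data.frame of excluded sample ids and their totals),
#'   `depth` and `seed`.
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  if (length(depth) != 1 || is.na(depth) || depth < 1 || depth != floor(depth))
    stop("depth must be a positive integer")
  m <- unclass(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep))
    stop(sprintf("all samples below depth %d (max total %d)",
                 as.integer(depth), as.integer(max(totals))))
  dropped <- data.frame(sample_id = rownames(m)[!keep],
                        total_reads = as.integer(totals[!keep]),
                        stringsAsFactors = FALSE)
  m <- m[keep, , drop = FALSE]
  totals <- totals[keep]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (totals[i] == depth) next
    reads <- rep.int(seq_len(ncol(m)), m[i, ])
    drawn <- sample(reads, depth)
    out[i, ] <- tabulate(drawn, nbins = ncol(m))
  }
  ft <- feature_table(out)
  list(table = ft, dropped_samples = dropped,
       depth = as.integer(depth), seed = as.integer(seed))
}
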