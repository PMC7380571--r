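# complete-case filter shared by the GLM workflow: samples missing the
# response or any covariate are dropped and reported, mirroring the field
# practice of excluding samples when an instrument (e.g. the chlorophyll
# fluorometer) fails. Missing values are NA, never 0.
.complete_cases <- function(response, design) {
  if (!is.data.frame(design)) design <- as.data.frame(design)
  if (length(response) != nrow(design))
    stop("response and design have different lengths")
  ok <- stats::complete.cases(design) & !is.na(response)
  list(response = response[ok], design = design[ok, , drop = FALSE],
       dropped = which(!ok))
}

.check_singular <- function(design) {
  X <- stats::model.matrix(~ ., data = design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  invisible(X)
}

#' Assumption gate for linear models on alpha diversity
#'
#' Fits the full additive model, then tests the residuals with the
#' Shapiro-Wilk normality test and the fit with the (classical,
#' non-studentized) Breusch-Pagan score test against the fitted values —
#' the `ncvTest` convention. A site/metric combination is admitted to the
#' driver analysis only when both p-values exceed 0.05.
#'
#' @param response numeric vector of per-sample alpha-diversity values.
#' @param design data.frame of covariates (one row per sample); rows with
#'   any missing value are dropped (complete-case policy) and reported.
#' @param log_transform log-transform the response before fitting (used for
#'   Faith's PD, whose raw values are typically right-skewed).
#' @return object of class `glm_gate`: `shapiro_p`, `breusch_pagan_p`,
#'   `transformed`, `admitted`, `n_used`, `dropped` (row indices removed as
#'   incomplete cases).
#' @export
glm_gate <- function(response, design, log_transform = FALSE) {
  cc <- .complete_cases(response, design)
  y <- cc$response
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires a strictly positive response")
    y <- log(y)
  }
  if (length(y) < ncol(cc$design) + 2L)
    stop("too few complete cases for the number of covariates")
  .check_singular(cc$design)
  fit <- stats::lm(y ~ ., data = cc$design)
  sh <- stats::shapiro.test(stats::residuals(fit))$p.value
  bp <- .bp_score_p(fit)
  structure(list(shapiro_p = unname(sh), breusch_pagan_p = unname(bp),
                 transformed = log_transform,
                 admitted = unname(sh > 0.05 && bp > 0.05),
                 n_used = length(y), dropped = cc$dropped),
            class = "glm_gate")
}

# classical (non-studentized) Breusch-Pagan / Cook-Weisberg score test of
# homoscedasticity against the fitted values: squared residuals, scaled by
# the ML variance estimate, are regressed on the fitted values; half the
# explained sum of squares is chi-squared with 1 df under the null
.bp_score_p <- function(fit) {
  e <- stats::residuals(fit)
  n <- length(e)
  u <- e^2 / (sum(e^2) / n)
  z <- stats::fitted(fit)
  aux <- stats::lm(u ~ z)
  stat <- sum((stats::fitted(aux) - mean(u))^2) / 2
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @export
print.glm_gate <- function(x, ...) {
  cat(sprintf("GLM assumption gate (n = %d%s)\n", x$n_used,
              if (x$transformed) ", log-transformed response" else ""))
  cat(sprintf("  Shapiro-Wilk residual normality p = %.4g\n", x$shapiro_p))
  cat(sprintf("  Breusch-Pagan homoscedasticity p = %.4g\n", x$breusch_pagan_p))
  cat(if (x$admitted) "  admitted\n" else "  NOT admitted\n")
  invisible(x)
}

#' Linear model of alpha diversity on environmental/biometric drivers
#'
#' Ordinary least squares with intercept of an alpha-diversity response on
#' the full additive covariate set, run only after the assumption gate
#' passes (or with an explicit, recorded `force`). Reports per-covariate
#' estimates, two-sided p-values and association signs, the adjusted and
#' multiple R-squared, the overall F statistic and p, and variance-inflation
#' factors (collinearity above VIF 10 is warned about, not auto-corrected).
#'
#' @inheritParams glm_gate
#' @param gate optional precomputed [glm_gate()] result for this
#'   response/design (recomputed when NULL).
#' @param force fit even when the gate rejects (flagged in the result).
#' @return object of class `glm_fit`: `coefficients` (data.frame term,
#'   estimate, std_error, p_value, sign, vif), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `p_value`, `n_used`, `gate`, `forced`.
#' @export
fit_glm <- function(response, design, log_transform = FALSE, gate = NULL,
                    force = FALSE) {
  if (is.null(gate)) gate <- glm_gate(response, design, log_transform)
  if (!gate$admitted && !force)
    stop(sprintf(paste0("assumption gate rejected this model ",
                        "(Shapiro p = %.4g, Breusch-Pagan p = %.4g); ",
                        "pass force = TRUE to fit anyway"),
                 gate$shapiro_p, gate$breusch_pagan_p))
  cc <- .complete_cases(response, design)
  y <- cc$response
  if (log_transform) y <- log(y)
  .check_singular(cc$design)
  fit <- stats::lm(y ~ ., data = cc$design)
  sm <- summary(fit)
  co <- sm$coefficients
  terms_only <- rownames(co) != "(Intercept)"
  vifs <- .vif(cc$design)
  coef_df <- data.frame(
    term = rownames(co)[terms_only],
    estimate = co[terms_only, "Estimate"],
    std_error = co[terms_only, "Std. Error"],
    p_value = co[terms_only, "Pr(>|t|)"],
    sign = ifelse(co[terms_only, "Estimate"] >= 0, "(+)", "(-)"),
    vif = vifs[rownames(co)[terms_only]],
    row.names = NULL, stringsAsFactors = FALSE)
  if (any(coef_df$vif > 10, na.rm = TRUE))
    warning("variance inflation factor above 10 for: ",
            paste(coef_df$term[coef_df$vif > 10], collapse = ", "))
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coef_df,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat["value"]),
    p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                               fstat["dendf"], lower.tail = FALSE)),
    n_used = length(y), gate = gate, forced = !gate$admitted,
    lm = fit), class = "glm_fit")
}

# variance inflation factors for a numeric covariate data.frame
.vif <- function(design) {
  vars <- names(design)
  if (length(vars) < 2)
    return(stats::setNames(rep(NA_real_, length(vars)), vars))
  out <- vapply(vars, function(v) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(vars, v), v),
                            data = design))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
  stats::setNames(out, vars)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Driver linear model (n = %d%s)\n", x$n_used,
              if (x$forced) ", gate overridden" else ""))
  cat(sprintf("  R2 = %.3f (adj %.3f), F = %.3f, p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$f_statistic, x$p_value))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the variation of a distance matrix among covariates using the
#' Gower-centered inner-product matrix of squared distances and sequential
#' (Type I, order-of-entry) sums of squares obtained by projection; term
#' order is therefore part of the analysis and is taken from the formula.
#' Significance is assessed by free permutation of the design rows:
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm). Deterministic
#' given `seed`.
#'
#' @param dm symmetric distance matrix with zero diagonal; dimnames are
#'   sample ids.
#' @param data data.frame of covariates, rows matching `dm` (matched by
#'   rownames when available, by position otherwise).
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ temperature + chlorophyll_a`.
#' @param n_perm number of permutations (>= 99).
#' @param seed permutation RNG seed.
#' @return object of class `permanova`: `table` (per-term Df, SumOfSqs, R2,
#'   F, p, plus Residual and Total rows), `overall_p`, `n_perm`, `seed`.
#' @export
permanova <- function(dm, data, formula, n_perm = 999L, seed = 1L) {
  validate_distance_matrix(dm)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!is.null(rownames(dm)) && !is.null(rownames(data)) &&
      all(rownames(dm) %in% rownames(data)))
    data <- data[rownames(dm), , drop = FALSE]
  else if (nrow(data) != nrow(dm))
    stop("design rows do not match distance matrix samples")
  n <- nrow(dm)
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) stop("formula has no terms")
  keep <- vapply(labels, function(l) {
    v <- data[[l]]
    is.null(v) || length(unique(v)) > 1
  }, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(labels[!keep], collapse = ", "))
    labels <- labels[keep]
    if (!length(labels)) stop("no non-constant covariates left")
  }
  X <- stats::model.matrix(stats::reformulate(labels), data = data)
  assign_idx <- attr(X, "assign")
  # Gower-centered inner-product matrix of squared distances
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12)
    stop("degenerate distance matrix: total sum of squares is zero")
  # cumulative hat matrices: intercept, then each added term
  hats <- vector("list", length(labels) + 1L)
  ranks <- integer(length(labels) + 1L)
  for (j in 0:length(labels)) {
    cols <- which(assign_idx <= j)
    Xj <- X[, cols, drop = FALSE]
    qr_j <- qr(Xj)
    Q <- qr.Q(qr_j)[, seq_len(qr_j$rank), drop = FALSE]
    hats[[j + 1L]] <- tcrossprod(Q)
    ranks[j + 1L] <- qr_j$rank
  }
  df_terms <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")
  ss_fun <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    ss_terms <- diff(tr)
    ss_res <- sum(diag(Gm)) - tr[length(tr)]
    f_terms <- (ss_terms / df_terms) / (ss_res / df_res)
    f_model <- (sum(ss_terms) / sum(df_terms)) / (ss_res / df_res)
    list(ss_terms = ss_terms, ss_res = ss_res, f_terms = f_terms,
         f_model = f_model)
  }
  obs <- ss_fun(G)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  exceed <- numeric(length(labels))
  exceed_model <- 0
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    perm <- ss_fun(G[p, p])
    exceed <- exceed + (perm$f_terms >= obs$f_terms)
    exceed_model <- exceed_model + (perm$f_model >= obs$f_model)
  }
  p_terms <- (1 + exceed) / (1 + n_perm)
  overall_p <- (1 + exceed_model) / (1 + n_perm)
  tab <- data.frame(
    term = c(labels, "Residual", "Total"),
    Df = c(df_terms, df_res, n - 1L),
    SumOfSqs = c(obs$ss_terms, obs$ss_res, ss_total),
    R2 = c(obs$ss_terms, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f_terms, NA, NA),
    p_value = c(p_terms, NA, NA),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, overall_p = overall_p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations, seed %d)\n",
              x$n_perm, x$seed))
  print(x$table, digits = 4)
  cat(sprintf("Overall p = %.4g\n", x$overall_p))
  invisible(x)
}

#' Community distance of body sites to environmental references
#'
#' Pools, per focal body site, all pairwise distances from that site's
#' samples to the samples of each environmental reference (seawater,
#' sediment), and tests — per reference — whether the focal groups differ
#' with a Kruskal-Wallis rank test. The ranking of the median distances
#' exposes exposure gradients (e.g. skin closest to seawater, digesta
#' closest to sediment).
#'
#' @param dm distance matrix over samples.
#' @param metadata sample metadata with `sample_id`, `sample_type`.
#' @param focal_types body-site sample types to compare (default the five
#'   mucosal sites).
#' @param reference_types environmental reference types (default seawater
#'   and sediment).
#' @return named list (one entry per reference) of lists with `distances`
#'   (data.frame focal, distance), `medians` (named vector),
#'   `kruskal_statistic`, `p_value`.
#' @export
group_distance_comparison <- function(dm, metadata,
                                      focal_types = fish_body_sites(),
                                      reference_types = c("seawater",
                                                          "sediment")) {
  validate_distance_matrix(dm)
  ids <- rownames(dm)
  md <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
  out <- list()
  for (ref in reference_types) {
    ref_ids <- md$sample_id[md$sample_type == ref]
    if (!length(ref_ids)) stop(sprintf("no samples of reference type '%s'", ref))
    pieces <- lapply(focal_types, function(f) {
      f_ids <- md$sample_id[md$sample_type == f]
      if (!length(f_ids)) stop(sprintf("no samples of focal type '%s'", f))
      data.frame(focal = f,
                 distance = as.numeric(dm[f_ids, ref_ids, drop = FALSE]),
                 stringsAsFactors = FALSE)
    })
    dists <- do.call(rbind, pieces)
    kw <- if (length(unique(dists$focal)) > 1 &&
              stats::var(dists$distance) > 0)
      stats::kruskal.test(distance ~ factor(focal), data = dists)
    else list(statistic = c(`Kruskal-Wallis chi-squared` = 0), p.value = 1)
    out[[ref]] <- list(
      distances = dists,
      medians = tapply(dists$distance, dists$focal, stats::median),
      kruskal_statistic = unname(kw$statistic),
      p_value = kw$p.value)
  }
  out
}
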