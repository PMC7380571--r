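test_that("gate decomposes into the stats tests it is built from", {
  set.seed(14)
  des <- study_design()
  y <- 2 + 0.1 * des$temperature + rnorm(nrow(des), 0, 0.5)
  g <- glm_gate(y, des)
  fit <- lm(y ~ ., data = des)
  expect_equal(g$shapiro_p, shapiro.test(residuals(fit))$p.value)
  # classical score test equals car::ncvTest and non-studentized bptest
  requireNamespace("car")
  suppressPackageStartupMessages(requireNamespace("lmtest"))
  expect_equal(g$breusch_pagan_p, car::ncvTest(fit)$p, tolerance = 1e-10)
  expect_identical(g$admitted, g$shapiro_p > 0.05 && g$breusch_pagan_p > 0.05)
})

test_that("gate admits well-specified Gaussian responses", {
  set.seed(15)
  n <- 150
  admitted <- vapply(1:200, function(i) {
    des <- data.frame(a = rnorm(n), b = runif(n, 1, 5), c = rnorm(n))
    y <- 1 + 0.4 * des$a - 0.2 * des$b + rnorm(n)
    glm_gate(y, des)$admitted
  }, logical(1))
  # two 5%-level checks pass jointly about 90% of the time under the null
  expect_gte(mean(admitted), 0.85)
})

test_that("gate flags heteroscedastic responses with high power at n = 200", {
  set.seed(16)
  n <- 200
  des <- data.frame(x1 = runif(n, 1, 5), x2 = rnorm(n))
  hits <- vapply(1:100, function(i) {
    y <- 1 + des$x1 + rnorm(n, 0, 0.8 * des$x1)   # sd proportional to x1
    glm_gate(y, des)$breusch_pagan_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("log transform rescues a log-normal response", {
  set.seed(17)
  des <- study_design(200)
  raw_adm <- log_adm <- logical(40)
  for (i in 1:40) {
    y <- exp(1 + 0.15 * des$temperature + rnorm(nrow(des), 0, 0.8))
    raw_adm[i] <- glm_gate(y, des)$admitted
    log_adm[i] <- glm_gate(y, des, log_transform = TRUE)$admitted
  }
  expect_gt(mean(log_adm), mean(raw_adm))
  expect_gte(mean(log_adm), 0.8)
})

test_that("complete-case policy drops and reports samples with missing covariates", {
  set.seed(18)
  des <- study_design(60)
  des$chlorophyll_a[c(3, 7)] <- NA
  y <- rnorm(60)
  g <- glm_gate(y, des)
  expect_equal(g$n_used, 58)
  expect_equal(g$dropped, c(3L, 7L))
})

test_that("fit_glm reproduces textbook OLS identities and refuses failed gates", {
  set.seed(19)
  des <- study_design(120)
  y <- 3 + 0.2 * des$temperature + rnorm(120, 0, 0.4)
  f <- suppressWarnings(fit_glm(y, des))
  k <- ncol(des); n <- 120
  r2 <- f$r_squared
  expect_equal(f$adj_r_squared, 1 - (1 - r2) * (n - 1) / (n - k - 1),
               tolerance = 1e-9)
  expect_equal(f$f_statistic, (r2 / k) / ((1 - r2) / (n - k - 1)),
               tolerance = 1e-9)
  # gate refusal without force
  yh <- exp(rnorm(120, 0, 2))
  expect_error(fit_glm(yh, des), "gate rejected")
  expect_s3_class(suppressWarnings(fit_glm(yh, des, force = TRUE)),
                  "glm_fit")
  # duplicated column is a singularity error naming the column
  des2 <- des; des2$temperature2 <- des2$temperature
  expect_error(suppressWarnings(fit_glm(y, des2, force = TRUE)), "collinear")
})

test_that("pure-noise responses give uniform overall p-values", {
  set.seed(20)
  des <- study_design(80)
  pvals <- vapply(1:300, function(i)
    suppressWarnings(fit_glm(rnorm(80), des, force = TRUE))$p_value,
    numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("planted driver coefficients are recovered with correct signs", {
  set.seed(21)
  des <- study_design(150)
  hit_t <- hit_c <- within2 <- logical(60)
  for (i in 1:60) {
    y <- 2 + 0.5 * des$temperature - 0.8 * des$chlorophyll_a + rnorm(150)
    f <- suppressWarnings(fit_glm(y, des, force = TRUE))   # expected VIF flag
    co <- f$coefficients
    rt <- co[co$term == "temperature", ]
    rc <- co[co$term == "chlorophyll_a", ]
    hit_t[i] <- rt$p_value < 0.05 && rt$sign == "(+)"
    hit_c[i] <- rc$p_value < 0.05 && rc$sign == "(-)"
    within2[i] <- abs(rt$estimate - 0.5) <= 2 * rt$std_error &&
      abs(rc$estimate + 0.8) <= 2 * rc$std_error
  }
  expect_gte(mean(hit_t), 0.8)
  expect_gte(mean(hit_c), 0.8)
  expect_gte(mean(within2), 0.8)
})

test_that("PERMANOVA pseudo-F equals one-way ANOVA F on a univariate embedding", {
  set.seed(22)
  y <- rnorm(24)
  g <- factor(rep(letters[1:3], each = 8))
  dm <- as.matrix(dist(y))
  dimnames(dm) <- list(paste0("s", 1:24), paste0("s", 1:24))
  df <- data.frame(g = g, row.names = rownames(dm))
  res <- permanova(dm, df, ~ g, n_perm = 99, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$table$F[1], f_aov, tolerance = 1e-9)
  # R2 partition sums to one
  expect_equal(sum(res$table$R2[res$table$term != "Total"]), 1,
               tolerance = 1e-9)
})

test_that("PERMANOVA matches vegan::adonis2 term-by-term", {
  set.seed(23)
  suppressPackageStartupMessages(requireNamespace("vegan"))
  x <- matrix(rpois(30 * 12, 4), 30, 12)
  rownames(x) <- paste0("s", 1:30)
  dm <- as.matrix(vegan::vegdist(x, "bray"))
  df <- data.frame(a = rnorm(30), b = factor(rep(1:3, 10)),
                   row.names = rownames(x))
  ours <- permanova(dm, df, ~ a + b, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(as.dist(dm) ~ a + b, data = df, by = "terms",
                        permutations = 999)
  expect_equal(ours$table$SumOfSqs, ref$SumOfSqs, tolerance = 1e-9)
  expect_equal(ours$table$R2, ref$R2, tolerance = 1e-9)
  expect_equal(ours$table$F[1:2], ref$F[1:2], tolerance = 1e-9)
  # permutation p-values agree within binomial error of 999 draws
  expect_lt(max(abs(ours$table$p_value[1:2] - ref$`Pr(>F)`[1:2])), 0.06)
})

test_that("PERMANOVA R2 is seed-invariant, p bounded, determinism holds", {
  set.seed(24)
  x <- matrix(rnorm(20 * 3), 20, 3)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("s", 1:20), paste0("s", 1:20))
  df <- data.frame(a = rnorm(20), row.names = rownames(dm))
  r1 <- permanova(dm, df, ~ a, n_perm = 199, seed = 1)
  r2 <- permanova(dm, df, ~ a, n_perm = 199, seed = 99)
  r3 <- permanova(dm, df, ~ a, n_perm = 199, seed = 1)
  expect_equal(r1$table$R2, r2$table$R2)
  expect_identical(r1$table$p_value, r3$table$p_value)
  expect_gte(r1$table$p_value[1], 1 / 200)
  expect_lte(r1$table$p_value[1], 1)
  # degenerate matrix and constant covariates are refused/dropped
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(permanova(zero, data.frame(a = rnorm(4),
                                          row.names = letters[1:4]),
                         ~ a, n_perm = 99), "degenerate")
  dfc <- data.frame(a = rnorm(20), b = 1, row.names = rownames(dm))
  expect_warning(permanova(dm, dfc, ~ a + b, n_perm = 99, seed = 1),
                 "constant")
})

test_that("group distance comparison ranks references and matches Kruskal-Wallis", {
  # three focal groups of one sample each: H from the textbook formula
  dm <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d <- c(0.2, 0.5, 0.9)
  dm[1:3, 4] <- d; dm[4, 1:3] <- d
  md <- data.frame(sample_id = paste0("s", 1:4),
                   sample_type = c("gill", "skin", "digesta", "seawater"),
                   stringsAsFactors = FALSE)
  res <- group_distance_comparison(dm, md,
                                   focal_types = c("gill", "skin", "digesta"),
                                   reference_types = "seawater")
  n <- 3; ranks <- rank(d)
  h_manual <- 12 / (n * (n + 1)) * sum((ranks - (n + 1) / 2)^2)
  expect_equal(res$seawater$kruskal_statistic, h_manual, tolerance = 1e-12)
  # identical distances: H = 0, p = 1
  dm2 <- dm; dm2[1:3, 4] <- 0.5; dm2[4, 1:3] <- 0.5
  res2 <- group_distance_comparison(dm2, md,
                                    focal_types = c("gill", "skin", "digesta"),
                                    reference_types = "seawater")
  expect_equal(res2$seawater$kruskal_statistic, 0)
  expect_equal(res2$seawater$p_value, 1)
  expect_error(group_distance_comparison(dm, md, focal_types = "GI",
                                         reference_types = "seawater"),
               "no samples")
})
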