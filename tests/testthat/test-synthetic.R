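small_cfg <- function(...) {
  study_config(n_events = 8, fish_per_event = 2, n_ratio_events = 4,
               seed = 101, ...)
}

test_that("generated studies satisfy the container invariants", {
  st <- generate_study(small_cfg())
  expect_silent(validate_feature_table(unclass(st$table)))
  expect_silent(validate_phylogeny(st$tree))
  expect_true(all(rowSums(st$table) == 5000))
  expect_setequal(colnames(st$table), st$tree$tip.label)
  expect_identical(sort(st$metadata$sample_id), sort(rownames(st$table)))
  # 5 body sites per fish + water + sediment per event
  expect_equal(nrow(st$metadata), 8 * (2 * 5 + 2))
})

test_that("the same master seed reproduces the study exactly", {
  a <- generate_study(small_cfg())
  b <- generate_study(small_cfg())
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$controls, b$controls)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_study(study_config(n_events = 8, fish_per_event = 2,
                                   n_ratio_events = 4, seed = 102))
  expect_false(identical(unclass(a$table), unclass(c$table)))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(55)
  x <- runif(1)
  set.seed(55)
  invisible(generate_study(small_cfg()))
  expect_identical(runif(1), x)
})

test_that("planted host:seawater ratios are recovered exactly from the table", {
  st <- generate_study(small_cfg())
  gt <- st$ground_truth
  res <- host_env_ratio_events(st$table, st$metadata, events = gt$ratio_events)
  expect_equal(res$per_event$ratio, gt$ratio$per_event$ratio)
  expect_equal(res$mean, gt$ratio$mean)
  expect_equal(res$range, gt$ratio$range)
})

test_that("uniqueness, gamma, core and bloom prevalence match construction", {
  st <- generate_study(small_cfg())
  gt <- st$ground_truth
  u <- uniqueness_by_event(st$table, st$metadata)
  expect_equal(as.numeric(u$mean_fraction[c("fish", "seawater", "sediment")]),
               as.numeric(gt$uniqueness$mean[c("fish", "seawater",
                                               "sediment")]))
  for (env in c("seawater", "sediment")) {
    ids <- st$metadata$sample_id[st$metadata$sample_type == env]
    expect_equal(gamma_richness(st$table, ids), gt$gamma[[env]])
  }
  for (tp in c("gill", "digesta")) {
    core <- core_features(st$table, st$metadata, tp, 0.30)
    expect_identical(sort(core$feature_id), gt$core[[tp]])
  }
  for (s in gt$bloom$sites) {
    gp <- group_prevalence(st$table, st$metadata, gt$bloom$feature, s)
    expect_equal(gp$prevalence, gt$bloom$prevalence[[s]])
  }
})

test_that("zero shared pools make every environment fully unique", {
  cfg <- small_cfg(shared_per_event = c(fish_water = 0L, water_sediment = 0L,
                                        fish_sediment = 0L))
  st <- generate_study(cfg)
  u <- uniqueness_by_event(st$table, st$metadata)
  expect_true(all(u$per_event$fraction == 1))
})

test_that("skin Shannon diversity tracks its planted covariate-driven target", {
  st <- generate_study(small_cfg())
  gt <- st$ground_truth
  ids <- names(gt$skin_target_shannon)
  realized <- apply(unclass(st$table)[ids, , drop = FALSE], 1, shannon)
  # the one-read presence floor adds a small, nearly constant entropy
  # offset; what matters for effect recovery is that realized entropy is an
  # affine, near-unit-slope function of the target
  fit <- lm(realized ~ target, data.frame(target = gt$skin_target_shannon))
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
  expect_lt(sd(resid(fit)), 0.1)
  expect_lt(max(abs(realized - gt$skin_target_shannon)), 0.2)
})

test_that("planted covariate effects on skin alpha diversity are recoverable", {
  st <- generate_study(study_config(seed = 31))
  md <- add_biometrics(st$metadata, growth_params(400, 0.45, -0.8))
  skin <- md[md$sample_type == "skin", ]
  y <- apply(unclass(st$table)[skin$sample_id, , drop = FALSE], 1, shannon)
  des <- skin[, c("age_yr", "fork_length_mm", "mass_kg", "condition_k",
                  "chlorophyll_a", "pressure", "salinity", "temperature")]
  f <- suppressWarnings(fit_glm(y, des, force = TRUE))
  co <- f$coefficients
  ae <- st$ground_truth$alpha_effect
  rt <- co[co$term == "temperature", ]
  rc <- co[co$term == "chlorophyll_a", ]
  expect_lte(abs(rt$estimate - ae$temperature), 2 * rt$std_error)
  expect_lte(abs(rc$estimate - ae$chlorophyll_a), 2 * rc$std_error)
  expect_identical(rt$sign, "(+)")
  expect_identical(rc$sign, "(-)")
})

test_that("the exposure gradient is visible in UniFrac distances", {
  st <- generate_study(small_cfg())
  al <- align_table_tree(st$table, st$tree)
  dm <- beta_distance_matrix(al$table, al$tree, "unweighted_unifrac")
  res <- group_distance_comparison(dm, st$metadata,
                                   focal_types = c("gill", "skin", "digesta"))
  # gill/skin sit closer to seawater than digesta; digesta closer to sediment
  expect_lt(res$seawater$medians[["skin"]], res$seawater$medians[["digesta"]])
  expect_lt(res$seawater$medians[["gill"]], res$seawater$medians[["digesta"]])
  expect_lt(res$sediment$medians[["digesta"]], res$sediment$medians[["skin"]])
  expect_lt(res$seawater$p_value, 0.05)
})

test_that("PERMANOVA detects the planted body-site structure", {
  st <- generate_study(small_cfg())
  al <- align_table_tree(st$table, st$tree)
  md <- st$metadata
  fish_ids <- md$sample_id[md$sample_type %in% c("gill", "skin", "digesta")]
  dm <- beta_distance_matrix(
    feature_table(unclass(al$table)[fish_ids, , drop = FALSE]),
    al$tree, "unweighted_unifrac")
  df <- data.frame(site = md[fish_ids, "sample_type"], row.names = fish_ids)
  res <- permanova(dm, df, ~ site, n_perm = 199, seed = 4)
  expect_lte(res$table$p_value[1], 0.01)
  expect_gt(res$table$R2[1], 0.1)
})

test_that("titration controls reflect the configured sigmoid and threshold", {
  st <- generate_study(small_cfg())
  gt <- st$ground_truth
  expect_equal(gt$titration$analytic_threshold, 1407L)
  cv <- fit_lod_curve(st$controls)
  thr <- exclusion_threshold(cv, 0.9)
  expect_lt(abs(thr - 1407) / 1407, 0.5)   # single noisy replicate, loose
})

test_that("ground truth survives the JSON round trip with full coverage", {
  st <- generate_study(small_cfg())
  path <- withr::local_tempfile(fileext = ".json")
  ground_truth_report(st$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(all(c("ratio", "uniqueness", "gamma", "core", "bloom",
                    "titration", "alpha_effect", "depth", "seed") %in%
                    names(back)))
  expect_equal(back$ratio$mean, st$ground_truth$ratio$mean)
  expect_equal(back$gamma$fish, st$ground_truth$gamma$fish)
  expect_equal(sort(back$core$gill), st$ground_truth$core$gill)
  expect_length(back$alpha_effect, 4)
})

test_that("write_study persists all five artifacts readably", {
  st <- generate_study(small_cfg())
  dir <- withr::local_tempdir()
  write_study(st, dir)
  tab <- read_feature_table(file.path(dir, "feature_table.tsv"))
  expect_identical(unclass(tab), unclass(st$table))
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(md$sample_id, st$metadata$sample_id)
  tr <- read_phylogeny(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, st$tree$tip.label)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
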