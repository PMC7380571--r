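test_that("gamma richness counts the union of presence sets", {
  ts <- tiny_study()
  expect_equal(gamma_richness(ts$table, "g1"), 2)
  expect_equal(gamma_richness(ts$table), 5)
  # identical samples add nothing
  expect_equal(gamma_richness(ts$table, c("g1", "g1")), 2)
  expect_error(gamma_richness(ts$table, character()), "empty")
  expect_error(gamma_richness(ts$table, "nope"), "nope")
})

test_that("accumulation curves match a step-by-step set-union oracle", {
  set.seed(11)
  m <- matrix(rbinom(6 * 20, 1, 0.3), 6, 20,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:20)))
  m[rowSums(m) == 0, 1] <- 1L
  storage.mode(m) <- "integer"
  tab <- feature_table(m)
  cur <- accumulation_curve(tab, paste0("s", 1:6))
  seen <- character()
  for (k in 1:6) {
    seen <- union(seen, colnames(m)[m[k, ] > 0])
    expect_equal(cur$richness[k], length(seen))
  }
  expect_true(all(diff(cur$richness) >= 0))
  expect_equal(cur$richness[6], attr(cur, "pooled_richness"))
  expect_error(accumulation_curve(tab, c("s1", "zz")), "unknown sample")
})

test_that("degenerate accumulation shapes: flat for identical, linear for disjoint", {
  ident <- feature_table(matrix(1L, 4, 3,
                                dimnames = list(paste0("s", 1:4),
                                                paste0("f", 1:3))))
  expect_equal(accumulation_curve(ident)$richness, rep(3, 4))
  disj <- matrix(0L, 3, 6, dimnames = list(paste0("s", 1:3), paste0("f", 1:6)))
  disj[1, 1:2] <- 1L; disj[2, 3:4] <- 1L; disj[3, 5:6] <- 1L
  expect_equal(accumulation_curve(feature_table(disj))$richness, c(2, 4, 6))
  # permuted policy on identical samples has zero spread
  perm <- accumulation_curve(ident, policy = "permuted", n_perm = 20)
  expect_equal(perm$sd, rep(0, 4))
})

test_that("saturation_n finds the crossing step and respects the permuted policy", {
  disj <- matrix(0L, 4, 8, dimnames = list(paste0("s", 1:4), paste0("f", 1:8)))
  for (i in 1:4) disj[i, (2 * i - 1):(2 * i)] <- 1L
  tab <- feature_table(disj)
  expect_equal(saturation_n(tab, fraction = 1.0)$n, 4)
  # one sample holding everything, placed first
  allin <- rbind(disj, s5 = rep(1L, 8))
  expect_equal(saturation_n(feature_table(allin),
                            order = c("s5", paste0("s", 1:4)))$n, 1)
  # permuted policy matches a brute-force scan of each ordering
  set.seed(12)
  res <- saturation_n(tab, fraction = 0.6, policy = "permuted",
                      n_perm = 30, seed = 5)
  # disjoint equal-size samples: 60% of 8 features needs ceiling(4.8/2)=3 samples
  expect_equal(res$n, 3)
  expect_equal(res$sd, 0)
  expect_error(saturation_n(tab, fraction = 0), "fraction")
})

test_that("host:seawater ratio is the union-to-water richness quotient", {
  fish <- list(gill = c("a", "b"), skin = c("b", "c"), digesta = c("d"))
  expect_equal(host_env_ratio(fish, c("x", "y")), 2)
  expect_equal(host_env_ratio(fish, fish$gill, body_sites = "gill"), 1)
  expect_error(host_env_ratio(fish[1:2], c("x")), "digesta")
  expect_error(host_env_ratio(fish, character()), "water richness")
})

test_that("uniqueness partition matches brute-force set differences", {
  sets <- list(A = c("1", "2", "3"), B = c("3", "4"), C = c("5"))
  part <- uniqueness_partition(sets)
  expect_equal(part$exclusive[part$environment == "A"], 2)
  expect_equal(part$fraction[part$environment == "B"], 0.5)
  expect_equal(part$fraction[part$environment == "C"], 1)
  # disjoint -> all 1; identical -> all 0
  expect_true(all(uniqueness_partition(list(a = "1", b = "2"))$fraction == 1))
  expect_true(all(uniqueness_partition(list(a = "1", b = "1"))$fraction == 0))
  expect_error(uniqueness_partition(list(a = character(), b = "1")), "empty")
  # order/relabel invariance
  part2 <- uniqueness_partition(rev(sets))
  expect_equal(part2$fraction[match(part$environment, part2$environment)],
               part$fraction)
})

test_that("core calling is inclusive at the threshold and nested across thresholds", {
  m <- matrix(0L, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  m[1:3, "a"] <- 1L         # exactly 30% prevalence
  m[1:10, "b"] <- 2L        # always present
  m[1, "c"] <- 1L
  m[rowSums(m) == 0, "b"] <- 1L
  md <- data.frame(sample_id = rownames(m), sample_type = "gill",
                   stringsAsFactors = FALSE)
  tab <- feature_table(m)
  core30 <- core_features(tab, md, "gill", 0.30)
  expect_setequal(core30$feature_id, c("a", "b"))   # boundary included
  core100 <- core_features(tab, md, "gill", 1.0)
  expect_setequal(core100$feature_id, "b")
  expect_true(all(core100$feature_id %in% core30$feature_id))
  # median relative abundance includes zero samples
  expect_equal(core30$median_rel_abundance[core30$feature_id == "a"], 0)
  expect_error(core_features(tab, md, "skin"), "no samples")
  expect_error(core_features(tab, md, "gill", 0), "prevalence")
})

test_that("group prevalence sums member features per sample", {
  ts <- tiny_study()
  # singleton group equals the per-feature computation
  gp <- group_prevalence(ts$table, ts$metadata, "a", "gill")
  expect_equal(gp$prevalence, 1)
  # group covering all features
  gp_all <- group_prevalence(ts$table, ts$metadata,
                             colnames(ts$table), "gill")
  expect_equal(gp_all$prevalence, 1)
  expect_equal(gp_all$median_rel_abundance, 1)
  gp_c <- group_prevalence(ts$table, ts$metadata, "c", "seawater")
  expect_equal(gp_c$prevalence, 0.5)
  expect_error(group_prevalence(ts$table, ts$metadata, character(), "gill"),
               "empty")
})

test_that("relative abundance floors zeros only in log-plot display", {
  expect_equal(relative_abundance(0), 0)
  expect_equal(relative_abundance(0, display = "log_plot"), 1e-5)
  expect_equal(relative_abundance(1362), 1)
  expect_equal(relative_abundance(681), 0.5)
  expect_equal(relative_abundance(c(0, 681), display = "log_plot"),
               c(1e-5, 0.5))
  expect_error(relative_abundance(2000), "exceeds")
})

test_that("accounting statistics agree with naive set oracles on random tables", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 50, 1, 0.15) * rpois(20 * 50, 3), 20, 50,
                dimnames = list(sprintf("s%02d", 1:20), sprintf("f%02d", 1:50)))
    m[rowSums(m) == 0, 1] <- 1L
    storage.mode(m) <- "integer"
    tab <- feature_table(m)
    sets <- lapply(seq_len(20), function(i) colnames(m)[m[i, ] > 0])
    expect_equal(gamma_richness(tab), length(unique(unlist(sets))))
    md <- data.frame(sample_id = rownames(m),
                     sample_type = rep(c("gill", "seawater"), each = 10),
                     stringsAsFactors = FALSE)
    prev_oracle <- colMeans(m[1:10, ] > 0)
    core <- core_features(tab, md, "gill", 0.30)
    expect_setequal(core$feature_id, names(prev_oracle)[prev_oracle >= 0.30])
  }
})
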