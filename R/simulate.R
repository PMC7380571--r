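#' Configuration for a synthetic mucosal-microbiome study
#'
#' Describes a full synthetic survey: chronological sampling events, several
#' fish per event each sampled at five mucosal body sites, one paired
#' seawater and one paired sediment sample per event, environmental and
#' biometric covariates, a dilution series of extraction-positive controls,
#' and the planted structure that gives every accounting statistic an exact
#' ground truth:
#' feature pools with environment-exclusive and shared blocks, a per-event
#' host:seawater richness-ratio preset (mean 3.2, range 1.7-5.2), planted
#' core blocks per sample type, an exposure gradient (gill/skin share
#' features with seawater, digesta with sediment), a summer-elevated bloom
#' feature emulating a seasonal pathogen, and a linear covariate effect on
#' skin Shannon diversity.
#'
#' @param n_events number of chronological sampling events (default 38).
#' @param fish_per_event fish sampled per event (default 5).
#' @param depth sequencing depth of every sample (reads; default 5000). A
#'   constant depth makes the study depth-comparable by construction, so
#'   rarefaction at this depth is the identity and planted presence sets are
#'   preserved exactly.
#' @param start_date ISO date of the first event; events are spaced evenly
#'   over one year.
#' @param pool_sizes named integer vector of feature-pool sizes:
#'   `fish`, `water`, `sediment` (environment-exclusive) and `fish_water`,
#'   `fish_sediment`, `water_sediment` (pairwise-shared blocks).
#' @param water_set_size features per seawater sample (default 100).
#' @param sediment_set_size features per sediment sample (default 150).
#' @param shared_per_event named integer vector: per-event draws from the
#'   shared pools — `fish_water` (in gill, skin and the seawater sample),
#'   `water_sediment`, `fish_sediment` (in digesta and the sediment sample).
#' @param site_set_size named integer vector of default per-sample feature
#'   set sizes for the five body sites.
#' @param core_size named integer vector: number of planted always-present
#'   (prevalence 1) features per sample type.
#' @param ratio_preset per-event host:seawater richness ratios planted at
#'   the `n_ratio_events` designated events (defaults: mean 3.2, range
#'   1.7-5.2).
#' @param n_ratio_events number of events carrying a planted ratio.
#' @param alpha_effect list planting the linear covariate effect on skin
#'   Shannon diversity (bits): `intercept`, `temperature` and
#'   `chlorophyll_a` slopes, residual `sigma`.
#' @param bloom list describing the seasonal bloom feature: `months`
#'   (calendar months of the bloom window), `sites` (body sites carrying
#'   it), `rel_abundance` (relative abundance when present).
#' @param titration list of limit-of-detection sigmoid parameters `f0`,
#'   `f1`, `m` (log10 reads), `h`, plus `n_controls`, `reads_min`,
#'   `reads_max` and `assay_reads` (reads scored per control, the binomial
#'   denominator of the noise).
#' @param growth a [growth_params()] object for the biometrics generator.
#' @param dirichlet_alpha symmetric Dirichlet concentration of the
#'   Dirichlet-multinomial count draws (small values = overdispersed,
#'   amplicon-like).
#' @param missing_chl_event event index whose chlorophyll a is reported
#'   missing (instrument-failure analogue); NA disables.
#' @param seed master seed; every stochastic component derives from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(
    n_events = 38L,
    fish_per_event = 5L,
    depth = 5000L,
    start_date = "2017-01-28",
    pool_sizes = c(fish = 700L, water = 250L, sediment = 300L,
                   fish_water = 60L, fish_sediment = 60L,
                   water_sediment = 40L),
    water_set_size = 100L,
    sediment_set_size = 150L,
    shared_per_event = c(fish_water = 25L, water_sediment = 13L,
                         fish_sediment = 8L),
    site_set_size = c(gill = 60L, skin = 60L, digesta = 80L, GI = 30L,
                      pyloric_ceca = 25L),
    core_size = c(gill = 20L, skin = 20L, digesta = 20L, GI = 15L,
                  pyloric_ceca = 15L, seawater = 25L, sediment = 25L),
    ratio_preset = c(1.7, 2.0, 2.3, 2.6, 2.9, 3.2, 3.5, 3.8, 4.8, 5.2),
    n_ratio_events = 10L,
    alpha_effect = list(intercept = 4.0, temperature = 0.12,
                        chlorophyll_a = -0.25, sigma = 0.25),
    bloom = list(months = 6:9, sites = c("skin", "digesta", "GI"),
                 rel_abundance = 0.03),
    titration = list(f0 = 0, f1 = 1, m = 2.3, h = 7, n_controls = 8L,
                     reads_min = 50L, reads_max = 100000L,
                     assay_reads = 200L),
    growth = growth_params(L_inf = 400, k = 0.45, t0 = -0.8),
    dirichlet_alpha = 0.3,
    missing_chl_event = NA_integer_,
    seed = 42L) {
  cfg <- as.list(environment())
  n_ratio_events <- min(n_ratio_events, n_events)
  cfg$n_ratio_events <- n_ratio_events
  cfg$ratio_events <- unique(round(seq(1, n_events,
                                       length.out = n_ratio_events)))
  cfg$ratio_preset <- rep_len(ratio_preset, length(cfg$ratio_events))
  # the three body-site core blocks plus the per-event shared draws are the
  # guaranteed floor of the selected fish's union; planted unions must
  # exceed it
  floor_union <- sum(core_size[c("gill", "skin", "digesta")]) +
    sum(shared_per_event[c("fish_water", "fish_sediment")])
  if (any(round(cfg$ratio_preset * water_set_size) < floor_union + 1))
    stop("ratio preset too small for the core/shared floor of the fish union")
  if (is.na(missing_chl_event) || missing_chl_event <= n_events)
    cfg$missing_chl_event <- missing_chl_event
  class(cfg) <- "study_config"
  cfg
}

.lod_threshold_analytic <- function(tit, target = 0.9) {
  ratio <- (tit$f1 - target) / (target - tit$f0)
  as.integer(ceiling(10^(tit$m / ratio^(1 / tit$h)) - 1e-9))
}

# Shannon (bits) of a k-point geometric abundance series with ratio theta
.geom_shannon <- function(theta, k) {
  if (theta >= 1) return(log2(k))
  w <- theta^(0:(k - 1L))
  p <- w / sum(w)
  p <- p[p > 0]          # 0 log 0 = 0; tiny theta underflows the tail
  -sum(p * log2(p))
}

# solve the geometric ratio producing a target Shannon value for k features
.solve_theta <- function(target, k) {
  if (target >= log2(k)) return(1)
  stats::uniroot(function(th) .geom_shannon(th, k) - target,
                 c(1e-8, 1 - 1e-12), tol = 1e-12)$root
}

# deterministic largest-remainder allocation of `depth` reads over
# probabilities p, with every feature guaranteed >= 1 read
.round_counts <- function(p, depth) {
  k <- length(p)
  rest <- depth - k
  raw <- p * rest
  cnt <- floor(raw)
  rem <- rest - sum(cnt)
  if (rem > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[idx] <- cnt[idx] + 1
  }
  as.integer(cnt + 1L)
}

# Dirichlet-multinomial counts over k features at fixed depth, presence
# guaranteed by a one-read floor per feature
.dm_counts <- function(k, depth, alpha) {
  w <- stats::rgamma(k, shape = alpha)
  if (sum(w) <= 0) w <- rep(1, k)
  as.integer(1L + stats::rmultinom(1L, depth - k, w / sum(w))[, 1L])
}

#' Generate a complete synthetic study
#'
#' Realizes a [study_config()]: builds the feature pools and a random
#' bifurcating phylogeny with exponential branch lengths over them, plants
#' per-event presence sets (exposure gradient, ratio preset, core blocks,
#' bloom feature), draws Dirichlet-multinomial counts with a one-read floor
#' on every planted feature so presence is deterministic, injects the
#' covariate effect on skin Shannon diversity by modulating abundance
#' evenness, simulates the titration controls, and records every planted
#' quantity in a ground-truth object. Fully reproducible from the master
#' seed; the caller's RNG state is untouched.
#'
#' @param config a [study_config()].
#' @return list with `table` ([feature_table()]), `metadata` (data.frame),
#'   `tree` ([ape::phylo]), `controls` (titration data.frame) and
#'   `ground_truth` (list; see [ground_truth_report()]).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  ps <- cfg$pool_sizes
  pools <- list(
    fish = sprintf("sF%04d", seq_len(ps[["fish"]])),
    water = sprintf("sW%04d", seq_len(ps[["water"]])),
    sediment = sprintf("sS%04d", seq_len(ps[["sediment"]])),
    fish_water = sprintf("sFW%03d", seq_len(ps[["fish_water"]])),
    fish_sediment = sprintf("sFS%03d", seq_len(ps[["fish_sediment"]])),
    water_sediment = sprintf("sWS%03d", seq_len(ps[["water_sediment"]])))
  bloom_id <- "sBLOOM01"
  all_features <- c(unlist(pools, use.names = FALSE), bloom_id)

  cs <- cfg$core_size
  core <- list(
    gill = pools$fish[seq_len(cs[["gill"]])],
    skin = pools$fish[cs[["gill"]] + seq_len(cs[["skin"]])],
    digesta = pools$fish[cs[["gill"]] + cs[["skin"]] + seq_len(cs[["digesta"]])],
    GI = pools$fish[cs[["gill"]] + cs[["skin"]] + cs[["digesta"]] +
                      seq_len(cs[["GI"]])],
    pyloric_ceca = pools$fish[cs[["gill"]] + cs[["skin"]] + cs[["digesta"]] +
                                cs[["GI"]] + seq_len(cs[["pyloric_ceca"]])],
    seawater = pools$water[seq_len(cs[["seawater"]])],
    sediment = pools$sediment[seq_len(cs[["sediment"]])])
  fish_rand <- setdiff(pools$fish, unlist(core[fish_body_sites()]))
  water_rand <- setdiff(pools$water, core$seawater)
  sed_rand <- setdiff(pools$sediment, core$sediment)

  # chronology and event-level covariates (seasonal temperature sinusoid,
  # lognormal chlorophyll a with spring bloom spikes, stationary salinity
  # and pressure)
  ne <- cfg$n_events
  dates <- as.Date(cfg$start_date) +
    round(seq(0, 363, length.out = ne))
  doy <- as.integer(format(dates, "%j"))
  months <- as.integer(format(dates, "%m"))
  temperature <- 17 + 3.5 * cos(2 * pi * (doy - 225) / 365) +
    stats::rnorm(ne, 0, 0.3)
  chl <- exp(stats::rnorm(ne, log(0.8), 0.3))
  spring <- which(months %in% 3:5)
  if (length(spring)) {
    spikes <- spring[seq_len(min(3L, length(spring)))]
    chl[spikes] <- chl[spikes] + stats::runif(length(spikes), 2, 3.5)
  }
  salinity <- stats::rnorm(ne, 33.4, 0.15)
  pressure <- stats::rnorm(ne, 2.5, 0.3)

  sh <- cfg$shared_per_event
  bloom_events <- which(months %in% cfg$bloom$months)
  ratio_lookup <- stats::setNames(cfg$ratio_preset, cfg$ratio_events)

  sets <- list()     # per-sample planted feature sets
  meta_rows <- list()
  gt_events <- list()
  skin_targets <- c()

  for (e in seq_len(ne)) {
    sfw <- sample(pools$fish_water, sh[["fish_water"]])
    sws <- sample(pools$water_sediment, sh[["water_sediment"]])
    sfs <- sample(pools$fish_sediment, sh[["fish_sediment"]])
    water_set <- c(core$seawater, sws, sfw,
                   sample(water_rand, cfg$water_set_size -
                            length(core$seawater) - length(sws) - length(sfw)))
    sed_set <- c(core$sediment, sws, sfs,
                 sample(sed_rand, cfg$sediment_set_size -
                          length(core$sediment) - length(sws) - length(sfs)))
    wid <- sprintf("E%02d.water", e)
    sid <- sprintf("E%02d.sed", e)
    sets[[wid]] <- water_set
    sets[[sid]] <- sed_set
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = c(wid, sid), sample_type = c("seawater", "sediment"),
      event_index = e, stringsAsFactors = FALSE)

    in_bloom <- e %in% bloom_events
    for (f in seq_len(cfg$fish_per_event)) {
      fid <- sprintf("E%02d.F%d", e, f)
      is_ratio_fish <- f == 1L && as.character(e) %in% names(ratio_lookup)
      if (is_ratio_fish) {
        # the planted union size of gill+skin+digesta fixes the
        # host:seawater ratio exactly; the bloom feature (if this event is
        # in the bloom window) is part of that union
        u <- round(ratio_lookup[[as.character(e)]] * cfg$water_set_size)
        floor_n <- length(core$gill) + length(core$skin) +
          length(core$digesta) + length(sfw) + length(sfs)
        extra_n <- u - floor_n - as.integer(in_bloom &&
          any(c("skin", "digesta") %in% cfg$bloom$sites))
        extra <- sample(fish_rand, extra_n)
        n_g <- round(0.3 * extra_n)
        n_s <- round(0.3 * extra_n)
        site_sets <- list(
          gill = c(core$gill, sfw, extra[seq_len(n_g)]),
          skin = c(core$skin, sfw, extra[n_g + seq_len(n_s)]),
          digesta = c(core$digesta, sfs, extra[(n_g + n_s + 1L):extra_n]),
          GI = c(core$GI, sample(fish_rand, cfg$site_set_size[["GI"]] -
                                   length(core$GI))),
          pyloric_ceca = c(core$pyloric_ceca,
                           sample(fish_rand,
                                  cfg$site_set_size[["pyloric_ceca"]] -
                                    length(core$pyloric_ceca))))
      } else {
        sz <- cfg$site_set_size
        site_sets <- list(
          gill = c(core$gill, sfw,
                   sample(fish_rand, sz[["gill"]] - length(core$gill) -
                            length(sfw))),
          skin = c(core$skin, sfw,
                   sample(fish_rand, sz[["skin"]] - length(core$skin) -
                            length(sfw))),
          digesta = c(core$digesta, sfs,
                      sample(fish_rand, sz[["digesta"]] -
                               length(core$digesta) - length(sfs))),
          GI = c(core$GI, sample(fish_rand, sz[["GI"]] - length(core$GI))),
          pyloric_ceca = c(core$pyloric_ceca,
                           sample(fish_rand, sz[["pyloric_ceca"]] -
                                    length(core$pyloric_ceca))))
      }
      if (in_bloom)
        for (s in cfg$bloom$sites)
          site_sets[[s]] <- c(site_sets[[s]], bloom_id)
      # fish biometrics: age drawn, length through the growth model with
      # mild lognormal measurement noise, mass through a condition factor
      age <- stats::runif(1, 0.7, 4)
      fl <- length_at_age(age, cfg$growth) * exp(stats::rnorm(1, 0, 0.02))
      fl <- min(fl, cfg$growth$L_inf * 0.99)
      k_cond <- stats::rnorm(1, 1.2, 0.08)
      mass_g <- k_cond / 100 * (fl / 10)^3
      for (s in names(site_sets)) {
        samp_id <- sprintf("%s.%s", fid, s)
        sets[[samp_id]] <- site_sets[[s]]
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          sample_id = samp_id, sample_type = s, event_index = e,
          fish_id = fid, fork_length_mm = fl, mass_kg = mass_g / 1000,
          stringsAsFactors = FALSE)
        if (s == "skin") {
          ae <- cfg$alpha_effect
          target <- ae$intercept + ae$temperature * (temperature[e] - 17) +
            ae$chlorophyll_a * (chl[e] - 1.5) +
            stats::rnorm(1, 0, ae$sigma)
          k_s <- length(site_sets$skin)
          skin_targets[samp_id] <- min(max(target, 0.3), log2(k_s) - 0.05)
        }
      }
      if (f == 1L) {
        env_sets <- list(
          fish = unique(unlist(site_sets[c("gill", "skin", "digesta")],
                               use.names = FALSE)),
          seawater = water_set, sediment = sed_set)
        part <- uniqueness_partition(env_sets)
        gt_events[[e]] <- data.frame(
          event = e,
          ratio = length(env_sets$fish) / length(water_set),
          fish_richness = length(env_sets$fish),
          water_richness = length(water_set),
          fish_unique = part$fraction[part$environment == "fish"],
          water_unique = part$fraction[part$environment == "seawater"],
          sediment_unique = part$fraction[part$environment == "sediment"],
          stringsAsFactors = FALSE)
      }
    }
  }

  metadata <- do.call(rbind, lapply(meta_rows, function(r) {
    for (col in c("fish_id", "fork_length_mm", "mass_kg"))
      if (is.null(r[[col]])) r[[col]] <- NA
    r
  }))
  metadata$collection_date <- dates[metadata$event_index]
  metadata$temperature <- temperature[metadata$event_index]
  metadata$salinity <- salinity[metadata$event_index]
  metadata$pressure <- pressure[metadata$event_index]
  metadata$chlorophyll_a <- chl[metadata$event_index]
  if (!is.na(cfg$missing_chl_event))
    metadata$chlorophyll_a[metadata$event_index == cfg$missing_chl_event] <-
      NA_real_
  metadata <- validate_sample_metadata(metadata)

  # counts: geometric-evenness allocation for skin (carries the planted
  # Shannon target), Dirichlet-multinomial for everything else; the bloom
  # feature gets its planted share off the top
  ids <- names(sets)
  m <- matrix(0L, length(ids), length(all_features),
              dimnames = list(ids, all_features))
  bloom_reads <- as.integer(round(cfg$bloom$rel_abundance * cfg$depth))
  for (i in seq_along(ids)) {
    s <- sets[[ids[i]]]
    has_bloom <- bloom_id %in% s
    s_main <- setdiff(s, bloom_id)
    d_main <- cfg$depth - if (has_bloom) bloom_reads else 0L
    k <- length(s_main)
    cnt <- if (ids[i] %in% names(skin_targets)) {
      theta <- .solve_theta(skin_targets[[ids[i]]], k)
      w <- theta^(0:(k - 1L))
      .round_counts(w / sum(w), d_main)
    } else {
      .dm_counts(k, d_main, cfg$dirichlet_alpha)
    }
    m[i, s_main] <- cnt
    if (has_bloom) m[i, bloom_id] <- bloom_reads
  }
  ftab <- feature_table(m)

  # titration controls: log-spaced read depths through the configured
  # sigmoid, binomial read-assignment noise
  tit <- cfg$titration
  reads <- round(10^seq(log10(tit$reads_min), log10(tit$reads_max),
                        length.out = tit$n_controls))
  p_true <- .lod_sigmoid(log10(reads), tit$f0, tit$f1, tit$m, tit$h)
  frac <- stats::rbinom(length(reads), tit$assay_reads, p_true) /
    tit$assay_reads
  controls <- data.frame(control_id = sprintf("ctrl%02d", seq_along(reads)),
                         total_reads = as.integer(reads),
                         fraction_correct = frac, stringsAsFactors = FALSE)

  tree <- ape::rtree(length(all_features), tip.label = sample(all_features),
                     br = function(n) stats::rexp(n, rate = 10))

  per_event <- do.call(rbind, gt_events)
  ratio_rows <- per_event[per_event$event %in% cfg$ratio_events, ]
  type_sets <- split(sets, metadata[ids, "sample_type"])
  gt_core <- lapply(type_sets, function(ss) {
    tab <- table(unlist(lapply(ss, unique), use.names = FALSE))
    prev <- as.numeric(tab) / length(ss)
    names(prev) <- names(tab)
    sort(names(prev)[prev >= 0.30])
  })
  gt_gamma <- c(
    lapply(type_sets, function(ss) length(unique(unlist(ss, use.names = FALSE)))),
    list(fish = length(unique(unlist(type_sets[fish_body_sites()],
                                     use.names = FALSE))),
         total = length(unique(unlist(sets, use.names = FALSE)))))
  bloom_prev <- vapply(cfg$bloom$sites, function(s) {
    ss <- type_sets[[s]]
    mean(vapply(ss, function(x) bloom_id %in% x, logical(1)))
  }, numeric(1))

  ground_truth <- list(
    seed = cfg$seed,
    depth = cfg$depth,
    n_events = ne,
    n_samples = length(ids),
    n_features = length(all_features),
    ratio_events = cfg$ratio_events,
    ratio = list(per_event = ratio_rows[, c("event", "ratio")],
                 mean = mean(ratio_rows$ratio),
                 range = range(ratio_rows$ratio)),
    uniqueness = list(
      per_event = per_event[, c("event", "fish_unique", "water_unique",
                                "sediment_unique")],
      mean = c(fish = mean(per_event$fish_unique),
               seawater = mean(per_event$water_unique),
               sediment = mean(per_event$sediment_unique))),
    gamma = gt_gamma,
    core = gt_core,
    bloom = list(feature = bloom_id, events = bloom_events,
                 months = cfg$bloom$months, sites = cfg$bloom$sites,
                 prevalence = as.list(bloom_prev),
                 reads = bloom_reads),
    alpha_effect = cfg$alpha_effect,
    skin_target_shannon = skin_targets,
    titration = c(tit[c("f0", "f1", "m", "h")],
                  analytic_threshold = .lod_threshold_analytic(tit)),
    missing_chl_event = cfg$missing_chl_event,
    growth = unclass(cfg$growth)[c("L_inf", "k", "t0")])

  list(table = ftab, metadata = metadata, tree = tree, controls = controls,
       ground_truth = ground_truth)
}

#' Write the ground-truth report as JSON
#'
#' Machine-readable record of every planted quantity of a generated study
#' (per-event ratios and uniqueness fractions with their means, gamma
#' richness per environment, core membership, bloom prevalence, planted
#' alpha-effect coefficients, titration parameters and analytic threshold),
#' so recovery tests can compare pipeline output against construction
#' rather than against another code path.
#'
#' @param ground_truth the `ground_truth` element of [generate_study()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
ground_truth_report <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a generated study to a directory
#'
#' Persists the four artifacts (feature-table TSV, metadata TSV, newick
#' tree, controls TSV) plus `ground_truth.json`.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(study$table, file.path(dir, "feature_table.tsv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_phylogeny(study$tree, file.path(dir, "tree.nwk"))
  utils::write.table(study$controls, file.path(dir, "controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ground_truth_report(study$ground_truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
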