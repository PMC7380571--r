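# Presence set of one sample (feature ids with >= 1 read). All accounting
# statistics treat >= 1 read in the (rarefied, depth-comparable) table as
# presence.
.presence_sets <- function(table, samples = NULL) {
  m <- unclass(table)
  if (is.null(samples)) samples <- rownames(m)
  bad <- setdiff(samples, rownames(m))
  if (length(bad)) stop(sprintf("unknown sample '%s'", bad[1L]))
  lapply(stats::setNames(samples, samples),
         function(s) colnames(m)[m[s, ] > 0])
}

#' Gamma richness of a sample selection
#'
#' Total number of distinct features observed (>= 1 read) across the
#' selected samples — the gamma diversity of that collection.
#'
#' @param table a [feature_table()].
#' @param samples character vector of sample ids (default: all samples).
#' @return integer richness.
#' @export
gamma_richness <- function(table, samples = NULL) {
  m <- unclass(table)
  if (is.null(samples)) samples <- rownames(m)
  if (!length(samples)) stop("empty sample selection")
  bad <- setdiff(samples, rownames(m))
  if (length(bad)) stop(sprintf("unknown sample '%s'", bad[1L]))
  sum(colSums(m[samples, , drop = FALSE] > 0) > 0)
}

#' Richness accumulation curve
#'
#' Cumulative number of distinct features as samples are added one at a
#' time. Under the `"chronological"` policy the caller-supplied ordering is
#' used as-is; under `"permuted"` the curve is averaged over `n_perm`
#' uniformly random orderings of the same samples and the per-step standard
#' deviation is reported.
#'
#' @param table a [feature_table()].
#' @param order character vector of sample ids giving the ordering (and the
#'   selection); defaults to the table's row order.
#' @param policy `"chronological"` or `"permuted"`.
#' @param n_perm number of random orderings for the permuted policy.
#' @param seed RNG seed for the permuted policy.
#' @return data.frame with columns `step`, `richness` (mean richness under
#'   the permuted policy) and, for the permuted policy, `sd`; the pooled
#'   richness is attached as attribute `"pooled_richness"`.
#' @export
accumulation_curve <- function(table, order = NULL,
                               policy = c("chronological", "permuted"),
                               n_perm = 100L, seed = 1L) {
  policy <- match.arg(policy)
  m <- unclass(table) > 0
  if (is.null(order)) order <- rownames(m)
  bad <- setdiff(order, rownames(m))
  if (length(bad)) stop(sprintf("ordering mentions unknown sample '%s'", bad[1L]))
  if (anyDuplicated(order)) stop("ordering repeats a sample")
  one_curve <- function(ord) {
    seen <- .cum_union(m[ord, , drop = FALSE])
    rowSums(seen)
  }
  pooled <- sum(colSums(m[order, , drop = FALSE]) > 0)
  if (policy == "chronological") {
    out <- data.frame(step = seq_along(order), richness = one_curve(order))
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    curves <- vapply(seq_len(n_perm),
                     function(i) one_curve(sample(order)),
                     numeric(length(order)))
    out <- data.frame(step = seq_along(order),
                      richness = rowMeans(curves),
                      sd = apply(curves, 1L, stats::sd))
  }
  attr(out, "pooled_richness") <- pooled
  out
}

# cumulative "seen so far" matrix: row k = union of first k rows
.cum_union <- function(x) {
  storage.mode(x) <- "integer"
  apply(x, 2L, cummax) -> cm
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = nrow(x))
  cm > 0
}

#' Saturation sample size
#'
#' Smallest number of samples whose cumulative richness reaches a given
#' fraction of the pooled richness of the selection. Under the permuted
#' policy the crossing step is found per random ordering and then averaged,
#' yielding a mean saturation n with its standard deviation.
#'
#' @inheritParams accumulation_curve
#' @param fraction target fraction of pooled richness (default 0.9).
#' @return list with `n` (mean over orderings; exact for chronological),
#'   `sd` (NA for chronological), `pooled_richness`, `fraction`.
#' @export
saturation_n <- function(table, order = NULL, fraction = 0.9,
                         policy = c("chronological", "permuted"),
                         n_perm = 100L, seed = 1L) {
  policy <- match.arg(policy)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- unclass(table) > 0
  if (is.null(order)) order <- rownames(m)
  bad <- setdiff(order, rownames(m))
  if (length(bad)) stop(sprintf("ordering mentions unknown sample '%s'", bad[1L]))
  pooled <- sum(colSums(m[order, , drop = FALSE]) > 0)
  target <- fraction * pooled
  crossing <- function(ord) {
    cum <- rowSums(.cum_union(m[ord, , drop = FALSE]))
    which(cum >= target)[1L]
  }
  if (policy == "chronological") {
    list(n = as.numeric(crossing(order)), sd = NA_real_,
         pooled_richness = pooled, fraction = fraction)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    ks <- vapply(seq_len(n_perm), function(i) crossing(sample(order)),
                 numeric(1))
    list(n = mean(ks), sd = stats::sd(ks), pooled_richness = pooled,
         fraction = fraction)
  }
}

#' Host-versus-seawater richness ratio
#'
#' Richness of the union of one fish's body-site feature sets divided by the
#' richness of the paired seawater sample — "how much microbial diversity is
#' in one unit of fish compared to one unit of seawater". Meaningful only at
#' a common rarefaction depth.
#'
#' @param fish_sets named list of character feature sets, one per body site.
#' @param water_set character feature set of the paired seawater sample.
#' @param body_sites body sites entering the union (default gill, skin,
#'   digesta — the three outward-facing high-diversity sites).
#' @return the ratio (a single number).
#' @export
host_env_ratio <- function(fish_sets, water_set,
                           body_sites = c("gill", "skin", "digesta")) {
  miss <- setdiff(body_sites, names(fish_sets))
  if (length(miss)) stop(sprintf("missing body site '%s'", miss[1L]))
  if (!length(water_set)) stop("water richness is zero")
  fish_union <- unique(unlist(fish_sets[body_sites], use.names = FALSE))
  length(fish_union) / length(water_set)
}

# select, per event, the fish (by fish_id) with the lowest sample id among
# its body-site samples that has every required site; returns metadata rows
.select_event_fish <- function(md, event, body_sites) {
  rows <- md[md$event_index == event & md$sample_type %in% body_sites, ,
             drop = FALSE]
  if (!nrow(rows)) return(NULL)
  split_rows <- split(rows, rows$fish_id)
  complete <- Filter(function(r) all(body_sites %in% r$sample_type), split_rows)
  if (!length(complete)) return(NULL)
  first_id <- vapply(complete, function(r) min(r$sample_id), character(1))
  complete[[names(first_id)[order(first_id)][1L]]]
}

#' Event-wise host:seawater richness ratios
#'
#' Evaluates [host_env_ratio()] for one fish plus the paired seawater sample
#' in each selected sampling event and reports the per-event ratios with
#' their mean and range. When an event holds several fish, the fish with the
#' lexicographically lowest sample id among complete-site fish is used — a
#' deterministic selection rule.
#'
#' @param table a [feature_table()] (rarefied to a common depth).
#' @param metadata sample metadata with `sample_id`, `sample_type`,
#'   `event_index` and `fish_id` columns.
#' @param events integer vector of event indices to use (default: every
#'   event holding a complete fish and a seawater sample).
#' @param body_sites body sites entering the fish union.
#' @return list with `per_event` (data.frame event, fish_id, fish_richness,
#'   water_richness, ratio), `mean` and `range`.
#' @export
host_env_ratio_events <- function(table, metadata, events = NULL,
                                  body_sites = c("gill", "skin", "digesta")) {
  md <- metadata
  if (!"fish_id" %in% names(md)) stop("metadata needs a fish_id column")
  if (is.null(events)) events <- sort(unique(md$event_index))
  rows <- list()
  for (ev in events) {
    fish <- .select_event_fish(md, ev, body_sites)
    water_ids <- md$sample_id[md$event_index == ev &
                              md$sample_type == "seawater"]
    if (is.null(fish) || !length(water_ids)) next
    water_id <- sort(water_ids)[1L]
    sets <- .presence_sets(table, fish$sample_id)
    names(sets) <- fish$sample_type
    wset <- .presence_sets(table, water_id)[[1L]]
    if (!length(wset)) stop(sprintf("water richness is zero in event %d", ev))
    fish_union <- unique(unlist(sets[body_sites], use.names = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      event = ev, fish_id = fish$fish_id[1L],
      fish_richness = length(fish_union), water_richness = length(wset),
      ratio = length(fish_union) / length(wset), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no event with a complete fish and seawater sample")
  per_event <- do.call(rbind, rows)
  list(per_event = per_event, mean = mean(per_event$ratio),
       range = range(per_event$ratio))
}

#' Uniqueness partition across environments
#'
#' For each environment, the number of its features found in no other
#' environment, and the exclusive fraction — the share of an environment's
#' microbes seen nowhere else.
#'
#' @param env_sets named list (>= 2 entries) of character feature sets.
#' @return data.frame with columns `environment`, `total`, `exclusive`,
#'   `fraction`.
#' @export
uniqueness_partition <- function(env_sets) {
  if (length(env_sets) < 2) stop("need at least two environments")
  if (is.null(names(env_sets)) || any(!nzchar(names(env_sets))))
    stop("environment sets must be named")
  empty <- names(env_sets)[!lengths(env_sets)]
  if (length(empty)) stop(sprintf("empty feature set for '%s'", empty[1L]))
  env_sets <- lapply(env_sets, unique)
  out <- lapply(names(env_sets), function(e) {
    others <- unique(unlist(env_sets[setdiff(names(env_sets), e)],
                            use.names = FALSE))
    excl <- sum(!(env_sets[[e]] %in% others))
    data.frame(environment = e, total = length(env_sets[[e]]),
               exclusive = excl, fraction = excl / length(env_sets[[e]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Event-wise uniqueness partition
#'
#' Builds, per sampling event, the feature sets of the fish environment
#' (union of one selected fish's body sites, same selection rule as
#' [host_env_ratio_events()]), the paired seawater sample and the paired
#' sediment sample, runs [uniqueness_partition()] on them, and averages the
#' exclusive fractions over events.
#'
#' @inheritParams host_env_ratio_events
#' @return list with `per_event` (long data.frame) and `mean_fraction`
#'   (named vector of event-averaged exclusive fractions).
#' @export
uniqueness_by_event <- function(table, metadata, events = NULL,
                                body_sites = c("gill", "skin", "digesta")) {
  md <- metadata
  if (!"fish_id" %in% names(md)) stop("metadata needs a fish_id column")
  if (is.null(events)) events <- sort(unique(md$event_index))
  rows <- list()
  for (ev in events) {
    fish <- .select_event_fish(md, ev, body_sites)
    water_ids <- sort(md$sample_id[md$event_index == ev &
                                   md$sample_type == "seawater"])
    sed_ids <- sort(md$sample_id[md$event_index == ev &
                                 md$sample_type == "sediment"])
    if (is.null(fish) || !length(water_ids) || !length(sed_ids)) next
    sets <- .presence_sets(table, fish$sample_id)
    names(sets) <- fish$sample_type
    env_sets <- list(
      fish = unique(unlist(sets[body_sites], use.names = FALSE)),
      seawater = .presence_sets(table, water_ids[1L])[[1L]],
      sediment = .presence_sets(table, sed_ids[1L])[[1L]])
    part <- uniqueness_partition(env_sets)
    part$event <- ev
    rows[[length(rows) + 1L]] <- part
  }
  if (!length(rows)) stop("no event with fish, seawater and sediment samples")
  per_event <- do.call(rbind, rows)
  mean_fraction <- c(tapply(per_event$fraction, per_event$environment, mean))
  list(per_event = per_event,
       mean_fraction = mean_fraction[unique(per_event$environment)])
}

#' Core-microbiome calling by prevalence
#'
#' Features present (>= 1 read) in at least `prevalence` of the samples of a
#' given sample type. The threshold is inclusive. Each core member is
#' reported with its prevalence and its median relative abundance across
#' ALL samples of the type — samples where the feature has zero reads enter
#' the median as zeros, so a core member seen in 30% of samples at modest
#' abundance will usually have median 0.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata with `sample_id` and `sample_type`.
#' @param sample_type the type whose core to call.
#' @param prevalence inclusive prevalence threshold in (0, 1\] (default
#'   0.30).
#' @return data.frame (`feature_id`, `prevalence`,
#'   `median_rel_abundance`), ordered by decreasing prevalence; attributes
#'   `sample_type`, `prevalence_threshold`, `n_samples`.
#' @export
core_features <- function(table, metadata, sample_type, prevalence = 0.30) {
  if (prevalence <= 0 || prevalence > 1)
    stop("prevalence must be in (0, 1]")
  ids <- metadata$sample_id[metadata$sample_type == sample_type]
  ids <- intersect(ids, rownames(table))
  if (!length(ids)) stop(sprintf("no samples of type '%s'", sample_type))
  m <- unclass(table)[ids, , drop = FALSE]
  prev <- colMeans(m > 0)
  rel <- m / rowSums(m)
  med <- apply(rel, 2L, stats::median)
  keep <- prev >= prevalence
  out <- data.frame(feature_id = colnames(m)[keep],
                    prevalence = as.numeric(prev[keep]),
                    median_rel_abundance = as.numeric(med[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "sample_type") <- sample_type
  attr(out, "prevalence_threshold") <- prevalence
  attr(out, "n_samples") <- length(ids)
  out
}

#' Prevalence and abundance of a feature group
#'
#' Treats a set of features (e.g. the sOTUs of one taxon of interest) as a
#' unit: per sample the group's reads are summed, prevalence is the fraction
#' of type-samples with at least one group read, and the median relative
#' abundance is taken over all type-samples (zeros included).
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata with `sample_id` and `sample_type`.
#' @param features non-empty character vector of member feature ids.
#' @param sample_type the sample type to summarise over.
#' @return list with `prevalence`, `median_rel_abundance`, `n_samples`.
#' @export
group_prevalence <- function(table, metadata, features, sample_type) {
  if (!length(features)) stop("empty feature group")
  ids <- metadata$sample_id[metadata$sample_type == sample_type]
  ids <- intersect(ids, rownames(table))
  if (!length(ids)) stop(sprintf("no samples of type '%s'", sample_type))
  m <- unclass(table)[ids, , drop = FALSE]
  bad <- setdiff(features, colnames(m))
  if (length(bad)) stop(sprintf("unknown feature '%s'", bad[1L]))
  grp <- rowSums(m[, features, drop = FALSE])
  list(prevalence = mean(grp >= 1),
       median_rel_abundance = stats::median(grp / rowSums(m)),
       n_samples = length(ids))
}

#' Relative abundance at rarefaction depth
#'
#' Reads divided by the rarefaction depth. In data exports a zero stays an
#' exact 0; only log-scale plot exports substitute the display floor
#' (default 1e-5) so undetected samples remain visible on the axis.
#'
#' @param reads integer read count(s), 0 <= reads <= depth.
#' @param depth rarefaction depth (default 1362).
#' @param display `"data"` (exact values) or `"log_plot"` (zeros replaced by
#'   `floor_display`).
#' @param floor_display substitute for zero under `"log_plot"`.
#' @return numeric relative abundance(s).
#' @export
relative_abundance <- function(reads, depth = 1362,
                               display = c("data", "log_plot"),
                               floor_display = 1e-5) {
  display <- match.arg(display)
  if (any(reads < 0)) stop("negative read count")
  if (any(reads > depth)) stop("read count exceeds rarefaction depth")
  ra <- reads / depth
  if (display == "log_plot") ra[ra == 0] <- floor_display
  ra
}
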