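# small in-code fixtures shared across test files

tiny_table <- function() {
  feature_table(matrix(c(5L, 0L, 1L, 3L), 2, 2, byrow = TRUE,
                       dimnames = list(c("s1", "s2"), c("f1", "f2"))))
}

# metadata + table pair with three sample types for accounting tests
tiny_study <- function() {
  m <- rbind(
    g1 = c(a = 1, b = 1, c = 0, d = 0, e = 0),
    g2 = c(a = 1, b = 0, c = 1, d = 0, e = 0),
    w1 = c(a = 0, b = 0, c = 1, d = 1, e = 0),
    w2 = c(a = 0, b = 0, c = 0, d = 1, e = 1))
  storage.mode(m) <- "integer"
  tab <- feature_table(m)
  md <- data.frame(
    sample_id = rownames(m),
    sample_type = c("gill", "gill", "seawater", "seawater"),
    event_index = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  list(table = tab, metadata = validate_sample_metadata(md))
}

# study-shaped covariate design for driver simulations: one generated
# study's skin covariates, reused read-only across tests
study_design <- local({
  cache <- NULL
  function(n = NULL) {
    if (is.null(cache)) {
      st <- generate_study(study_config(seed = 20260921))
      md <- add_biometrics(st$metadata, growth_params(400, 0.45, -0.8))
      skin <- md[md$sample_type == "skin", ]
      cache <<- skin[, c("age_yr", "fork_length_mm", "mass_kg",
                         "condition_k", "chlorophyll_a", "pressure",
                         "salinity", "temperature")]
    }
    if (is.null(n)) cache else cache[seq_len(n), ]
  }
})
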