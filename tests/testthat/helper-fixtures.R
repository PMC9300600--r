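# Shared fixtures, built in code.

# minimal participant rows with defaults that satisfy the schema
make_participants <- function(n, sex = "male", age = 40, ...) {
  base <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                     sex = sex, age = age, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

# wrap bare values as a standardized biomarker vector
as_biomarker <- function(values, name = "b") {
  zscore(structure(
    list(name = name, values = as.numeric(values), mu = NA_real_,
         sigma = NA_real_, zscores = rep(NA_real_, length(values)),
         n = sum(!is.na(values)), units = "", group = NA_character_),
    class = "biomarker_vector"))
}

# cohort where each distinct biomarker value occupies its own grid cell and
# per-cell prevalence is an exact (deterministic) function of that value:
# maps whose slope is known without sampling error. prev_at must return
# percentages giving integer counts at n_per_cell.
exact_linear_pmap <- function(prev_at, n_per_cell = 100,
                              values = seq(10, 35, by = 5)) {
  v <- rep(values, each = n_per_cell)
  vec <- as_biomarker(v)
  g <- make_grid(vec)
  idx <- norse:::bin_index(vec$zscores, g)
  stopifnot(length(unique(idx)) == length(values))
  p <- prev_at(v) / 100
  stopifnot(all(p >= 0 & p <= 1))
  flags <- numeric(length(v))
  for (u in unique(idx)) {
    pos <- which(idx == u)
    k <- round(p[pos[1]] * length(pos))
    flags[pos] <- c(rep(1, k), rep(0, length(pos) - k))
  }
  list(vec = vec, grid = g,
       pmap = build_pmap(vec, flags, list(g), min_cell = 1, min_frac = 0))
}
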