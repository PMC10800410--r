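# Small programmatic fixtures shared across test files.

tiny_panel_df <- function() {
  tibble::tibble(
    person_id = "p1",
    day = c(0L, 0L, 0L),
    slot = c("morning", "afternoon", "evening"),
    stress = c(2, 3, 1),
    na = c(1.4, 2.2, 1.0),
    pa = c(3.0, 2.8, 3.6)
  )
}

write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}

# A small simulated study at reduced size for estimator-adjacent tests.
small_study <- function(n_persons = 30, seed = 42, outcome = "na",
                        missing_rate = 0.102, n_days = 21) {
  simulate_study(generator_config(
    n_persons = n_persons, n_days = n_days, missing_rate = missing_rate,
    params = default_dsem_params(outcome), seed = seed
  ))
}

# Item matrix with given responses filled row-wise per person.
item_matrix <- function(rows, ids = paste0("p", seq_len(nrow(rows)))) {
  m <- as.matrix(rows)
  rownames(m) <- ids
  colnames(m) <- sprintf("item_%02d", seq_len(ncol(m)))
  m
}
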