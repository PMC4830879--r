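# Shared test fixtures and an independent re-reading of the calibration CSV
# used as an oracle against the package's own loader/likelihood path.

the_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- load_staging_table()
    tab
  }
})

# Independent parse of the packaged calibration: symbol matrix per temperature,
# read with plain read.csv and not via load_staging_table().
raw_calibration <- function() {
  path <- system.file("extdata", "staging_table.csv", package = "eggclock")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
}

# Symbol -> default representative presence probability (independent mapping).
q_from_symbol <- function(sym) {
  if (identical(sym, "")) return(0.01)
  if (identical(sym, "+")) return(0.125)
  if (identical(sym, "++")) return(0.5)
  if (identical(sym, "+++")) return(0.875)
  stop("bad symbol: ", sym)
}

# Full observation vector: every landmark absent except those named present.
full_observation <- function(present_ids, table, ...) {
  st <- stats::setNames(rep("absent", nrow(table$landmarks)),
                        table$landmarks$id)
  st[present_ids] <- "present"
  observation_set(st, table = table, ...)
}

# Brute-force log-likelihood over the 11 intervals computed straight from the
# CSV symbols, bypassing the package's staging/likelihood code.
brute_loglik <- function(statuses, temp_c) {
  raw <- raw_calibration()
  raw <- raw[as.numeric(raw$temp_c) == temp_c, ]
  cat_cols <- paste0("cat_", seq(0, 100, by = 10))
  ll <- numeric(11)
  for (k in seq_len(11)) {
    for (id in names(statuses)) {
      if (statuses[[id]] == "not_assessed") next
      sym <- raw[raw$landmark_id == id, cat_cols[k]]
      q <- q_from_symbol(sym)
      ll[k] <- ll[k] + if (statuses[[id]] == "present") log(q) else log(1 - q)
    }
  }
  ll
}
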