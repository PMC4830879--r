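# Staging calibration: the landmark x interval x temperature visibility map
# for Calliphora vicina embryogenesis, plus the interval -> Drosophila
# melanogaster stage correspondence (Campos-Ortega & Hartenstein numbering).

# Ordinal visibility levels, in developmental-frequency order.
VISIBILITY_LEVELS <- c("absent", "rare", "common", "prevalent")

.symbol_to_level <- c("absent", "rare", "common", "prevalent")
names(.symbol_to_level) <- c("", "+", "++", "+++")

.level_to_symbol <- c(absent = "", rare = "+", common = "++", prevalent = "+++")

# Admissible ranges for the representative presence probability of each
# category. The "absent" range is a mis-scoring floor, not a frequency class.
.category_ranges <- list(
  absent    = c(0, 0.05),
  rare      = c(0, 0.25),
  common    = c(0.25, 0.75),
  prevalent = c(0.75, 1)
)

# Canonical landmark set: id -> scorable after hot water killing + 80% ethanol.
.canonical_landmarks <- c(
  homogeneous_yolk_mass = FALSE,
  clear_gaps = FALSE,
  bright_peripheral_ring = TRUE,
  cephalic_furrow = TRUE,
  dorsal_folds = FALSE,
  stomodeal_invagination = TRUE,
  thoracic_segmentation = TRUE,
  clypeolabrum = TRUE,
  abdominal_segmentation = TRUE,
  sack_shaped_gut = TRUE,
  coil_shaped_gut = TRUE,
  spine_bands = TRUE,
  posterior_spiracles = TRUE,
  cephalopharyngeal_skeleton = TRUE,
  fully_developed_tracheal_system = FALSE
)

.interval_labels <- paste0(seq(0, 100, by = 10), "%")

.make_intervals <- function() {
  idx <- 0:10
  data.frame(
    index = idx,
    proportion_lo = idx / 10,
    proportion_hi = pmin(1, (idx + 1) / 10),
    label = .interval_labels,
    stringsAsFactors = FALSE
  )
}

#' Load the embryonic staging calibration table
#'
#' Reads the landmark visibility calibration (one row per landmark and
#' temperature, eleven ordinal category columns `cat_0` ... `cat_100` holding
#' the symbols `""`, `"+"`, `"++"`, `"+++"`) together with the per-temperature
#' development durations, validates it, and returns a queryable staging table.
#'
#' Blank cells encode "character not visible" at that interval. The packaged
#' canonical calibration holds 15 landmarks, eleven 10% developmental
#' intervals, and two calibrated temperatures (7.3 and 25 degrees C with total
#' egg development of 120 h and 16 h respectively, lower developmental
#' threshold 1 degree C).
#'
#' @param path Path to the staging calibration CSV. Defaults to the packaged
#'   canonical table.
#' @param calibration Path to the temperature calibration CSV with columns
#'   `temp_c`, `total_duration_h`, `base_temp_c`.
#' @param check_canonical Validate the canonical invariants (exactly the 15
#'   known landmarks, 11 of them visible after hot-water-killing fixation,
#'   every interval diagnosable at each temperature). Set `FALSE` to load
#'   experimental calibrations for other populations.
#' @return An object of class `staging_table`: a list with elements
#'   `landmarks` (data frame: `id`, `name`, `hwk_visible`), `intervals`
#'   (data frame: `index`, `proportion_lo`, `proportion_hi`, `label`),
#'   `temperatures` (data frame: `temp_c`, `total_duration_h`, `base_temp_c`)
#'   and `cells` (landmark x interval x temperature character array of
#'   visibility levels `"absent"`, `"rare"`, `"common"`, `"prevalent"`).
#' @examples
#' tab <- load_staging_table()
#' nrow(tab$landmarks)                      # 15
#' tab$cells["bright_peripheral_ring", "20%", "25"]
#' @export
load_staging_table <- function(path = eggclock_fixture("staging_table.csv"),
                               calibration = eggclock_fixture("calibration.csv"),
                               check_canonical = TRUE) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  cat_cols <- paste0("cat_", seq(0, 100, by = 10))
  needed <- c("landmark_id", "landmark_name", "hwk_visible", "temp_c", cat_cols)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_input("staging table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }

  cal <- utils::read.csv(calibration, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("temp_c", "total_duration_h", "base_temp_c") %in% names(cal))) {
    stop_input("calibration file must have columns temp_c, total_duration_h, base_temp_c")
  }
  cal <- cal[order(cal$temp_c), , drop = FALSE]
  if (any(cal$total_duration_h <= 0)) {
    stop_input("calibration: total_duration_h must be positive")
  }
  if (any(cal$temp_c <= cal$base_temp_c)) {
    stop_input("calibration: temp_c must exceed base_temp_c")
  }

  temps_chr <- as.character(cal$temp_c)
  row_temp <- as.numeric(raw$temp_c)
  if (anyNA(row_temp)) stop_input("staging table: non-numeric temp_c value")
  unknown_t <- setdiff(unique(row_temp), cal$temp_c)
  if (length(unknown_t) > 0) {
    stop_input("staging table references uncalibrated temperature(s): ",
               paste(unknown_t, collapse = ", "))
  }

  ids <- unique(raw$landmark_id)
  if (any(ids == "")) stop_input("staging table: empty landmark_id")

  # every landmark must appear exactly once per calibrated temperature
  for (id in ids) {
    for (tc in cal$temp_c) {
      n <- sum(raw$landmark_id == id & row_temp == tc)
      if (n == 0) {
        stop_input("landmark '", id, "' is missing its ", tc,
                   " C temperature block")
      }
      if (n > 1) {
        stop_input("duplicate rows for landmark '", id, "' at ", tc, " C")
      }
    }
  }
  extra <- nrow(raw) - length(ids) * nrow(cal)
  if (extra != 0) stop_input("staging table has unexpected extra rows")

  hwk <- toupper(raw$hwk_visible) %in% c("TRUE", "YES", "1")
  # hwk flag must agree across temperature blocks of the same landmark
  for (id in ids) {
    if (length(unique(hwk[raw$landmark_id == id])) != 1) {
      stop_input("landmark '", id, "' has inconsistent hwk_visible flags")
    }
  }

  cells <- array(NA_character_,
                 dim = c(length(ids), 11, nrow(cal)),
                 dimnames = list(ids, .interval_labels, temps_chr))
  for (r in seq_len(nrow(raw))) {
    tc <- temps_chr[match(row_temp[r], cal$temp_c)]
    for (k in seq_along(cat_cols)) {
      sym <- raw[[cat_cols[k]]][r]
      pos <- match(sym, names(.symbol_to_level))
      if (is.na(pos)) {
        stop_input("invalid visibility symbol '", sym, "' at landmark '",
                   raw$landmark_id[r], "', interval ", .interval_labels[k],
                   ", temperature ", raw$temp_c[r], " C")
      }
      cells[raw$landmark_id[r], k, tc] <- .symbol_to_level[[pos]]
    }
  }

  first_rows <- match(ids, raw$landmark_id)
  landmarks <- data.frame(
    id = ids,
    name = raw$landmark_name[first_rows],
    hwk_visible = hwk[first_rows],
    stringsAsFactors = FALSE
  )

  table <- structure(
    list(
      landmarks = landmarks,
      intervals = .make_intervals(),
      temperatures = cal,
      cells = cells
    ),
    class = "staging_table"
  )
  validate_staging_table(table, canonical = check_canonical)
  table
}

#' Validate a staging table's structural invariants
#'
#' @param table A `staging_table`.
#' @param canonical Also enforce the canonical invariants of the packaged
#'   calibration: exactly the 15 known landmark ids, exactly 11 of them
#'   `hwk_visible`, two calibrated temperatures, and every interval
#'   diagnosable (at least one landmark scored above "absent") at each
#'   temperature.
#' @return The table, invisibly; validation failures raise an error naming the
#'   offending landmark/interval/temperature.
#' @export
validate_staging_table <- function(table, canonical = TRUE) {
  stopifnot(inherits(table, "staging_table"))
  if (anyNA(table$cells)) stop_input("staging table has unfilled cells")
  bad <- !table$cells %in% VISIBILITY_LEVELS
  if (any(bad)) stop_input("staging table has cells with unknown levels")
  if (anyDuplicated(table$landmarks$id)) {
    stop_input("duplicate landmark ids")
  }
  if (!canonical) return(invisible(table))

  want <- names(.canonical_landmarks)
  miss <- setdiff(want, table$landmarks$id)
  if (length(miss) > 0) {
    stop_input("canonical landmark(s) missing: ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(table$landmarks$id, want)
  if (length(unknown) > 0) {
    stop_input("unknown landmark id(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(table$landmarks) != 15) {
    stop_input("expected 15 landmarks, found ", nrow(table$landmarks))
  }
  got_hwk <- table$landmarks$hwk_visible
  names(got_hwk) <- table$landmarks$id
  if (sum(got_hwk) != 11) {
    stop_input("expected exactly 11 HWK-visible landmarks, found ",
               sum(got_hwk))
  }
  flipped <- want[.canonical_landmarks != got_hwk[want]]
  if (length(flipped) > 0) {
    stop_input("hwk_visible flag wrong for: ", paste(flipped, collapse = ", "))
  }
  if (nrow(table$temperatures) != 2) {
    stop_input("canonical calibration must hold exactly two temperatures")
  }
  # every interval diagnosable at each temperature
  for (tc in dimnames(table$cells)[[3]]) {
    for (k in seq_len(11)) {
      if (all(table$cells[, k, tc] == "absent")) {
        stop_input("interval ", .interval_labels[k], " at ", tc,
                   " C has no diagnostic landmark")
      }
    }
  }
  invisible(table)
}

#' Serialize a staging table back to its CSV calibration format
#'
#' Writes the same row-per-landmark-and-temperature layout that
#' [load_staging_table()] reads, so that a load/write cycle reproduces the
#' calibration cell-for-cell.
#'
#' @param table A `staging_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_staging_table <- function(table, path) {
  stopifnot(inherits(table, "staging_table"))
  temps_chr <- dimnames(table$cells)[[3]]
  rows <- list()
  for (i in seq_len(nrow(table$landmarks))) {
    for (tj in seq_along(temps_chr)) {
      lev <- table$cells[table$landmarks$id[i], , temps_chr[tj]]
      row <- c(
        landmark_id = table$landmarks$id[i],
        landmark_name = table$landmarks$name[i],
        hwk_visible = as.character(table$landmarks$hwk_visible[i]),
        temp_c = as.character(table$temperatures$temp_c[tj]),
        stats::setNames(unname(.level_to_symbol[lev]),
                        paste0("cat_", seq(0, 100, by = 10)))
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a developmental interval to Drosophila embryonic stages
#'
#' Returns the embryonic stages of Campos-Ortega & Hartenstein's
#' *Drosophila melanogaster* staging that correspond to one of the eleven 10%
#' developmental intervals of *C. vicina* embryogenesis. Stages that fall only
#' partly inside the interval (stage 16 spans the 80% and 90% intervals;
#' stages 5 and 6 are only entered by the most advanced 20%-interval embryos)
#' are reported under `partial` rather than weighted fractionally.
#'
#' @param interval Interval index, an integer in 0..10 (0 = oviposition
#'   interval "0%", 10 = hatching interval "100%").
#' @return A list with integer vectors `full` and `partial` of stage numbers
#'   (1..17).
#' @examples
#' drosophila_stages(5)   # 50% interval -> stage 12
#' @export
drosophila_stages <- function(interval) {
  if (!is_scalar_number(interval) || interval %% 1 != 0 ||
      interval < 0 || interval > 10) {
    stop_input("interval index must be a single integer in 0..10")
  }
  map <- list(
    list(full = 1L, partial = integer(0)),            # 0%
    list(full = 2L, partial = integer(0)),            # 10%
    list(full = c(3L, 4L), partial = c(5L, 6L)),      # 20%
    list(full = c(6L, 7L, 8L, 9L), partial = integer(0)), # 30%
    list(full = c(10L, 11L), partial = integer(0)),   # 40%
    list(full = 12L, partial = integer(0)),           # 50%
    list(full = 13L, partial = integer(0)),           # 60%
    list(full = c(14L, 15L), partial = integer(0)),   # 70%
    list(full = integer(0), partial = 16L),           # 80%
    list(full = integer(0), partial = 16L),           # 90%
    list(full = 17L, partial = integer(0))            # 100%
  )
  map[[interval + 1L]]
}

#' @export
print.staging_table <- function(x, ...) {
  cat("Staging table:", nrow(x$landmarks), "landmarks,",
      nrow(x$intervals), "intervals,",
      nrow(x$temperatures), "temperatures\n")
  cat("  HWK-visible landmarks:", sum(x$landmarks$hwk_visible), "of",
      nrow(x$landmarks), "\n")
  for (j in seq_len(nrow(x$temperatures))) {
    cat(sprintf("  %g C: %g h oviposition to hatching (%.1f ADH, base %g C)\n",
                x$temperatures$temp_c[j], x$temperatures$total_duration_h[j],
                (x$temperatures$temp_c[j] - x$temperatures$base_temp_c[j]) *
                  x$temperatures$total_duration_h[j],
                x$temperatures$base_temp_c[j]))
  }
  invisible(x)
}
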