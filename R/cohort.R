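#' Canonical host-variability grid
#'
#' The three host parameters varied to emulate between-subject variability:
#' epithelial thickness `he` (how long drug takes to reach the stroma), gel
#' dilution rate `kD` (ambient vaginal fluid production and leakage), and
#' stroma-to-blood transport rate `kB` (stromal vascular architecture). The
#' default is five evenly informative levels per parameter, a 5 x 5 x 5 = 125
#' case full factorial.
#'
#' @param he_levels epithelial thicknesses, micrometres.
#' @param kD_levels gel dilution rates, 1/hr.
#' @param kB_levels stroma-to-blood rates, 1/hr.
#' @return object of class `variation_grid`.
#' @export
#' @examples
#' nrow(enumerate_cases(variation_grid())) # 125
variation_grid <- function(he_levels = c(100, 175, 250, 325, 400),
                           kD_levels = c(0.386, 0.515, 0.686, 0.915, 1.220),
                           kB_levels = c(0.067, 0.089, 0.119, 0.159, 0.212)) {
  g <- list(he_levels = he_levels, kD_levels = kD_levels,
            kB_levels = kB_levels)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)) || any(v <= 0))
      stop("grid levels for '", sub("_levels$", "", nm),
           "' must be positive and non-empty", call. = FALSE)
    if (anyDuplicated(v))
      stop("duplicate levels in '", sub("_levels$", "", nm), "'",
           call. = FALSE)
  }
  class(g) <- "variation_grid"
  g
}

#' Enumerate the full factorial of a variation grid
#'
#' Deterministic order: `he` outermost, `kD` middle, `kB` innermost.
#'
#' @param grid a [variation_grid()].
#' @return data.frame with columns `case`, `he`, `kD`, `kB`, one row per
#'   combination.
#' @export
enumerate_cases <- function(grid) {
  stopifnot(inherits(grid, "variation_grid"))
  df <- expand.grid(kB = grid$kB_levels, kD = grid$kD_levels,
                    he = grid$he_levels, KEEP.OUT.ATTRS = FALSE)
  df <- df[, c("he", "kD", "kB")]
  cbind(case = seq_len(nrow(df)), df)
}

#' Run the simulator over every case of a variation grid
#'
#' For each (he, kD, kB) triple the base parameter set is updated, the
#' transport model is solved, and the blood TFV PK metrics, stromal TFV PK
#' metrics and stromal percent-protected PD metrics are extracted.
#'
#' @param grid a [variation_grid()].
#' @param base base [transport_params()]; the three varied fields are
#'   overwritten per case.
#' @param disc a [discretization()].
#' @param t_end AUC horizon passed to [pk_metrics()].
#' @param progress print one line per case.
#' @return data.frame of class `cohort_dataset`: columns `case`, `he`, `kD`,
#'   `kB`, `blood_Cmax`, `blood_tmax`, `blood_AUC`, `blood_C24`,
#'   `stroma_Cmax`, `stroma_tmax`, `stroma_AUC`, `stroma_C24`, `t_lag`,
#'   `PPmax`. Attribute `provenance` records the solver settings. If any
#'   case fails, an error of class `mucosim_cohort_error` is signalled whose
#'   condition carries the completed rows in `$partial` and the failing
#'   parameter triples in `$failed`.
#' @export
run_cohort <- function(grid = variation_grid(), base = transport_params(),
                       disc = discretization(), t_end = max(disc$output_times),
                       progress = FALSE) {
  cases <- enumerate_cases(grid)
  rows <- vector("list", nrow(cases))
  failed <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- base
    p$he <- cs$he; p$kD <- cs$kD; p$kB <- cs$kB
    row <- tryCatch({
      res <- simulate_transport(p, disc)
      tt <- res$times
      bl <- pk_metrics(volume_average(res, "blood"), tt, t_end)
      st <- pk_metrics(volume_average(res, "stroma"), tt, t_end)
      pd <- pd_metrics(percent_protected(res), tt)
      data.frame(case = cs$case, he = cs$he, kD = cs$kD, kB = cs$kB,
                 blood_Cmax = bl$Cmax, blood_tmax = bl$tmax,
                 blood_AUC = bl$AUC, blood_C24 = bl$C24,
                 stroma_Cmax = st$Cmax, stroma_tmax = st$tmax,
                 stroma_AUC = st$AUC, stroma_C24 = st$C24,
                 t_lag = pd$t_lag, PPmax = pd$PPmax)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      failed[[length(failed) + 1L]] <-
        list(case = cs$case, he = cs$he, kD = cs$kD, kB = cs$kB,
             message = conditionMessage(row))
    } else {
      rows[[i]] <- row
    }
    if (progress)
      message(sprintf("case %d/%d: he=%g kD=%g kB=%g %s",
                      i, nrow(cases), cs$he, cs$kD, cs$kB,
                      if (inherits(row, "error")) "FAILED" else "ok"))
  }
  partial <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(failed)) {
    triples <- vapply(failed, function(f)
      sprintf("case %d (he=%g, kD=%g, kB=%g): %s",
              f$case, f$he, f$kD, f$kB, f$message), character(1))
    cond <- structure(
      class = c("mucosim_cohort_error", "error", "condition"),
      list(message = paste0(length(failed), " cohort case(s) failed:\n",
                            paste(triples, collapse = "\n")),
           call = sys.call(-1), partial = partial, failed = failed))
    stop(cond)
  }
  attr(partial, "provenance") <- list(
    base = unclass(base), disc = unclass(disc), t_end = t_end,
    n_cases = nrow(cases))
  class(partial) <- c("cohort_dataset", "data.frame")
  partial
}

#' Split a cohort dataset into training and test partitions
#'
#' The test partition receives `floor(fractions[2] * n)` rows drawn uniformly
#' at random under `seed`; the remainder trains. The split is disjoint,
#' exhaustive and reproducible.
#'
#' @param dataset a data.frame (e.g. from [run_cohort()]).
#' @param fractions length-2 positive numeric `(train, test)` summing to 1.
#' @param seed integer RNG seed.
#' @return list with data.frames `train`, `test` and the integer row
#'   indices `test_idx`.
#' @export
split_dataset <- function(dataset, fractions = c(0.8, 0.2), seed = 20190114) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0L)
    stop("dataset must be a non-empty data.frame", call. = FALSE)
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be two positive numbers summing to 1",
         call. = FALSE)
  n <- nrow(dataset)
  n_test <- floor(fractions[2] * n)
  if (n_test == 0L || n_test == n)
    stop("split leaves an empty partition (n = ", n, ", test = ", n_test, ")",
         call. = FALSE)
  test_idx <- sort(with_local_seed(seed, sample.int(n, n_test)))
  list(train = dataset[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE],
       test_idx = test_idx)
}

# evaluate expr under a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a cohort dataset as CSV
#'
#' Stable schema: the column order documented in [run_cohort()].
#'
#' @param dataset a `cohort_dataset` (or compatible data.frame).
#' @param path CSV path.
#' @return `path` invisibly ([write_cohort_csv()]); the data.frame
#'   ([read_cohort_csv()]).
#' @export
write_cohort_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- cohort_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  class(df) <- c("cohort_dataset", "data.frame")
  df
}

cohort_columns <- function() {
  c("case", "he", "kD", "kB",
    "blood_Cmax", "blood_tmax", "blood_AUC", "blood_C24",
    "stroma_Cmax", "stroma_tmax", "stroma_AUC", "stroma_C24",
    "t_lag", "PPmax")
}

blood_feature_columns <- function()
  c("blood_Cmax", "blood_tmax", "blood_AUC", "blood_C24")

stroma_output_columns <- function()
  c("stroma_Cmax", "stroma_tmax", "stroma_AUC", "stroma_C24",
    "t_lag", "PPmax")
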