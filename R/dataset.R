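#' Define a CCD process factor
#'
#' A factor in a central composite design is described by its centre value in
#' actual (physical) units and the size of one coded step, so that
#' \code{actual = center + coded * step} holds exactly at every design point.
#'
#' @param name short factor label, e.g. \code{"dose"}.
#' @param units physical units of the actual scale, e.g. \code{"g/L"}.
#' @param center actual value at coded 0.
#' @param step actual-unit change per coded unit; must be positive.
#' @param axial_level coded magnitude of the axial (star) points; 2 for the
#'   packaged design.
#' @return an object of class \code{factor_spec}.
#' @examples
#' fs <- factor_spec("dose", "g/L", center = 0.7, step = 0.3)
#' code_factor(1.3, fs)   # +2
#' @export
factor_spec <- function(name, units, center, step, axial_level = 2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(step), length(step) == 1L, step > 0)
  structure(
    list(name = name, units = units, center = center, step = step,
         axial_level = as.integer(axial_level)),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s [%s]: center %g, step %g, axial +/-%d\n",
              x$name, x$units, x$center, x$step, x$axial_level))
  invisible(x)
}

#' Factor specifications of the packaged As(III) biosorption design
#'
#' The four process factors of the packaged 31-run CCD: biosorbent dose
#' (centre 0.7 g/L, step 0.3), solution pH (6, 2), temperature (35 degC, 5)
#' and initial As(III) concentration (0.7 mg/L, 0.3).
#'
#' @return named list of four \code{\link{factor_spec}} objects, in the
#'   canonical order dose, ph, temp, conc.
#' @export
ccd_factors <- function() {
  list(
    dose = factor_spec("dose", "g/L",  center = 0.7, step = 0.3),
    ph   = factor_spec("ph",   "",     center = 6,   step = 2),
    temp = factor_spec("temp", "degC", center = 35,  step = 5),
    conc = factor_spec("conc", "mg/L", center = 0.7, step = 0.3))
}

#' Coded/actual factor transforms
#'
#' \code{code_factor} maps actual units to coded design units
#' (\code{(actual - center) / step}); \code{decode_factor} is its exact
#' inverse.
#'
#' @param actual,coded numeric vectors.
#' @param spec a \code{\link{factor_spec}}.
#' @return numeric vector.
#' @export
code_factor <- function(actual, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  (actual - spec$center) / spec$step
}

#' @rdname code_factor
#' @export
decode_factor <- function(coded, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  spec$center + coded * spec$step
}

run_columns <- c("dose", "ph", "temp", "conc",
                 "removal_obs", "removal_reg", "removal_ann", "split")

#' Construct a CCD dataset
#'
#' Bundles a run table (factor settings in actual units, observed percentage
#' removal, optional reference prediction columns, and a train/test split
#' flag) with the four factor specifications.
#'
#' @param runs data frame with columns \code{dose}, \code{ph}, \code{temp},
#'   \code{conc}, \code{removal_obs} and optionally \code{removal_reg},
#'   \code{removal_ann}, \code{split}.
#' @param factors list of four \code{\link{factor_spec}}s
#'   (default \code{\link{ccd_factors}}).
#' @return object of class \code{ccd_dataset}: a list with elements
#'   \code{runs} and \code{factors}.
#' @export
ccd_dataset <- function(runs, factors = ccd_factors()) {
  stopifnot(is.data.frame(runs), length(factors) == 4L)
  needed <- c("dose", "ph", "temp", "conc", "removal_obs")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols))
    stop("CCD run table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"removal_reg" %in% names(runs)) runs$removal_reg <- NA_real_
  if (!"removal_ann" %in% names(runs)) runs$removal_ann <- NA_real_
  if (!"split" %in% names(runs)) runs$split <- "train"
  for (cc in setdiff(run_columns, "split")) {
    if (!is.numeric(runs[[cc]]))
      stop("column '", cc, "' must be numeric", call. = FALSE)
  }
  if (!all(runs$split %in% c("train", "test")))
    stop("split flags must be 'train' or 'test'", call. = FALSE)
  bad <- which(runs$removal_obs < 0 | runs$removal_obs > 100)
  if (length(bad))
    stop("removal_obs outside [0, 100] at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(runs = runs[, run_columns], factors = factors),
            class = "ccd_dataset")
}

#' @export
print.ccd_dataset <- function(x, ...) {
  cat(sprintf("<ccd_dataset> %d runs (%d train, %d test)\n",
              nrow(x$runs), sum(x$runs$split == "train"),
              sum(x$runs$split == "test")))
  for (f in x$factors)
    cat(sprintf("  %-5s center %g %s, step %g\n",
                f$name, f$center, f$units, f$step))
  invisible(x)
}

#' Coded design matrix of a CCD dataset
#'
#' @param dataset a \code{\link{ccd_dataset}}.
#' @return numeric matrix (n x 4) of coded factor values, columns
#'   \code{x1..x4} in factor order.
#' @export
coded_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ccd_dataset"))
  m <- mapply(function(col, spec) code_factor(dataset$runs[[col]], spec),
              c("dose", "ph", "temp", "conc"), dataset$factors)
  m <- matrix(m, ncol = 4, dimnames = list(NULL, paste0("x", 1:4)))
  # snap float noise so factorial/axial levels compare exactly
  round(m, 10)
}

#' The packaged 31-run As(III) biosorption CCD
#'
#' The full-factorial central composite design used throughout the package
#' as the canonical worked example: 16 factorial, 8 axial (coded magnitude 2)
#' and 7 centre-replicate runs over biosorbent dose, pH, temperature and
#' initial As(III) concentration, with the observed percentage removal and
#' the study's regression- and neural-network-predicted removals as reference
#' columns. 24 runs are flagged \code{train} and 7 \code{test}, the split
#' used to fit the neural-network surrogate.
#'
#' @return a \code{\link{ccd_dataset}} of 31 runs.
#' @examples
#' d <- table2_ccd()
#' table(d$runs$split)
#' @export
table2_ccd <- function() {
  path <- system.file("extdata", "ccd_table2.csv", package = "biosorb",
                      mustWork = TRUE)
  read_ccd_csv(path)
}

csv_schema <- c(dose_g_per_L = "dose", pH = "ph", temp_C = "temp",
                conc_mg_per_L = "conc", removal_pct = "removal_obs",
                removal_reg_pct = "removal_reg",
                removal_ann_pct = "removal_ann", split = "split")

#' Read / write CCD datasets as CSV
#'
#' File schema (header required, "." decimal separator):
#' \code{dose_g_per_L, pH, temp_C, conc_mg_per_L, removal_pct}
#' and optionally \code{removal_reg_pct, removal_ann_pct, split}.
#'
#' @param path file path.
#' @param dataset a \code{\link{ccd_dataset}}.
#' @param factors factor specs to attach on read (default
#'   \code{\link{ccd_factors}}).
#' @return \code{read_ccd_csv} returns a \code{\link{ccd_dataset}};
#'   \code{write_ccd_csv} invisibly returns \code{path}.
#' @export
read_ccd_csv <- function(path, factors = ccd_factors()) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  required <- names(csv_schema)[1:5]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  runs <- data.frame(row.names = seq_len(nrow(raw)))
  for (src in names(csv_schema)) {
    dst <- csv_schema[[src]]
    if (!src %in% names(raw)) next
    if (dst == "split") { runs[[dst]] <- raw[[src]]; next }
    vals <- suppressWarnings(as.numeric(raw[[src]]))
    bad <- which(is.na(vals) & !(is.na(raw[[src]]) | raw[[src]] == ""))
    if (length(bad))
      stop("non-numeric value in column '", src, "' at data row ",
           bad[1], call. = FALSE)
    runs[[dst]] <- vals
  }
  ccd_dataset(runs, factors)
}

#' @rdname read_ccd_csv
#' @export
write_ccd_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ccd_dataset"))
  out <- dataset$runs
  names(out) <- names(csv_schema)[match(names(out), csv_schema)]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
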