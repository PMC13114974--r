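#' Load the 30-sample GC-MS vs ANN comparison cohort
#'
#' The packaged fixture holds, verbatim at the printed two-decimal
#' precision, the 30-fecal-sample comparison of GC-MS reference
#' concentrations and neural-network predictions (total SCFAs, propionate,
#' butyrate, all in mM), the prediction uncertainties, and the printed
#' relative deviations in percent. The loader checksums the table against a
#' frozen column sum and row count before returning it.
#'
#' One printed deviation is internally inconsistent: sample 2's total
#' deviation prints +0.4% while the printed concentrations imply +2.4%.
#' The fixture keeps the printed value; the row index is exposed via the
#' `inconsistent_dev` attribute so downstream checks can flag it.
#'
#' @return A 30-row data frame with columns `sample_no`, `gc_total`,
#'   `gc_prop`, `gc_but`, `ann_total`, `ann_prop`, `ann_but`, `u_total`,
#'   `u_prop`, `u_but`, `dev_total`, `dev_prop`, `dev_but`.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "scfavolt",
                      mustWork = TRUE)
  x <- utils::read.csv(path)
  expect_cols <- c("sample_no", "gc_total", "gc_prop", "gc_but",
                   "ann_total", "ann_prop", "ann_but",
                   "u_total", "u_prop", "u_but",
                   "dev_total", "dev_prop", "dev_but")
  if (!identical(names(x), expect_cols) || nrow(x) != 30L ||
      abs(sum(as.matrix(x)) - 1133.53) > 1e-6) {
    stop("table2 fixture is corrupted")
  }
  attr(x, "inconsistent_dev") <- data.frame(sample_no = 2L,
                                            analyte = "total",
                                            printed = 0.4, implied = 2.4)
  x
}

#' Load the standard-mixture calibration anchors
#'
#' Printed mean +/- SD descriptor values (n = 3 replicates) for the three
#' calibration descriptors measured in standard mixtures: the propionate
#' area B_A1 at 0-3 mM, the butyrate current C_I1 at 0-3 mM, and the
#' total-SCFA half-wave area A_A1 at 0-20 mM. These anchors define the
#' synthetic generator's descriptor-concentration relations.
#'
#' @return A data frame with columns `descriptor`, `analyte`, `conc_mM`,
#'   `mean`, `sd`, `n`, `units`.
#' @export
load_calibration_anchors <- function() {
  path <- system.file("extdata", "fig3_anchors.csv", package = "scfavolt",
                      mustWork = TRUE)
  x <- utils::read.csv(path)
  if (nrow(x) != 13L || any(x$n != 3L) ||
      abs(sum(x$mean) + sum(x$sd) - 6148.23) > 1e-6) {
    stop("calibration-anchor fixture is corrupted")
  }
  for (d in c("B_A1", "C_I1", "A_A1")) {
    m <- x$mean[x$descriptor == d][order(x$conc_mM[x$descriptor == d])]
    if (any(diff(m) <= 0)) stop("anchor means must increase with concentration")
  }
  x
}

#' Assemble a Table-1-shaped modeling dataset
#'
#' Builds the train/test split used for model development: the
#' propionate/butyrate dataset has 72 training cases (18 fecal-matrix cases
#' plus 54 non-real cases) and 30 fecal test cases; the total-SCFA dataset
#' has 156 training cases (30 fecal plus 126 non-real) and the same-shaped
#' 30-sample fecal test set. The composition of the non-real cases is
#' selectable: `"augmented"` (default) draws them from the fecal-matrix
#' generator so the training set covers the distortion distribution the
#' test set is drawn from; `"standard"` draws clean standard-mixture cases
#' without matrix distortion. Everything is reproducible from the seed in
#' `cfg`.
#'
#' @param kind `"pb"` (propionate/butyrate) or `"total"`.
#' @param cfg a [synth_config()]; its `seed` fixes the dataset.
#' @param nonreal composition of the non-real training cases (see above).
#' @return A list with data frames `train` and `test` (feature columns,
#'   ground-truth and reference concentrations, `origin`, `split`), plus
#'   `sizes`.
#' @export
build_dataset <- function(kind = c("pb", "total"), cfg = synth_config(),
                          nonreal = c("augmented", "standard")) {
  kind <- match.arg(kind)
  nonreal <- match.arg(nonreal)
  n_nonreal <- if (kind == "pb") 54L else 126L
  n_fec_train <- if (kind == "pb") 18L else 30L
  n_test <- 30L
  aug <- generate_cohort(n_nonreal, cfg, fecal = nonreal == "augmented",
                         seed_offset = 1L, id_prefix = nonreal)
  fec <- generate_cohort(n_fec_train, cfg, fecal = TRUE,
                         seed_offset = 2L, id_prefix = "fec")
  tst <- generate_cohort(n_test, cfg, fecal = TRUE,
                         seed_offset = 3L, id_prefix = "test")
  aug$origin <- nonreal; fec$origin <- "fecal"; tst$origin <- "fecal"
  train <- rbind(aug, fec)
  train$split <- "train"; tst$split <- "test"
  list(train = train, test = tst,
       sizes = c(train = nrow(train), test = nrow(tst)))
}
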