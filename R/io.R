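#' Write a DWI phantom to NIfTI with an FSL-style bval sidecar
#'
#' @param phantom a `dwi_phantom`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dwi_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(signal = file.path(dir, "dwi.nii.gz"),
             bvals = file.path(dir, "dwi.bval"))
  RNifti::writeNifti(phantom$signal, paths["signal"])
  writeLines(paste(phantom$b_values, collapse = " "), paths["bvals"])
  for (nm in c("true_adc_map", "true_ddc_map", "true_alpha_map", "s0_map")) {
    p <- file.path(dir, paste0(sub("_map$", "", sub("^true_", "truth_", nm)), ".nii.gz"))
    RNifti::writeNifti(phantom[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a 4D DWI series with its bval sidecar
#'
#' @param nii path to a 4D NIfTI file.
#' @param bvals path to a whitespace-separated b-value file (one value per
#'   volume, FSL convention).
#' @return List with `signal` (4D array) and `b_values`.
#' @export
read_dwi_data <- function(nii, bvals) {
  signal <- as.array(RNifti::readNifti(nii))
  b <- scan(bvals, quiet = TRUE)
  if (length(dim(signal)) != 4L || dim(signal)[4] != length(b)) {
    stop("bval sidecar does not match the 4th NIfTI axis")
  }
  list(signal = signal, b_values = b)
}

#' Write / read a per-lesion cohort table as CSV
#'
#' The schema is
#' `id,set,label,age,sex,smoking,diameter_mm,suvmax,mtv_ml,tlg_g,adc,ddc,alpha,mtrasym_pct`.
#'
#' @param table cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort` invisibly returns `path`; `read_cohort` returns
#'   the validated data.frame.
#' @export
write_cohort <- function(table, path) {
  cols <- c("id", "set", "label", "age", "sex", "smoking", "diameter_mm",
            "suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("id", "set", "label", "age", "sex", "smoking", "diameter_mm",
            "suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")
  missing <- setdiff(cols, names(tab))
  if (length(missing)) stop("cohort CSV lacks columns: ", paste(missing, collapse = ", "))
  tab
}

#' Save / load a fitted prediction model as JSON
#'
#' Stores the selected predictors, per-SD coefficients, training
#' standardisation statistics and odds-ratio table, so a model fitted on one
#' cohort can score another.
#'
#' @param model an `spl_logistic` model.
#' @param path JSON path.
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored `spl_logistic`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spl_logistic"))
  obj <- list(predictors = model$predictors,
              coefficients = as.list(model$coefficients),
              scaling = lapply(model$scaling, as.list),
              or_table = model$or_table,
              positive = model$positive,
              separation = model$separation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(predictors = as.character(obj$predictors),
                 coefficients = unlist(obj$coefficients),
                 or_table = as.data.frame(obj$or_table),
                 trace = NULL,
                 scaling = lapply(obj$scaling, unlist),
                 positive = obj$positive,
                 separation = isTRUE(obj$separation)),
            class = "spl_logistic")
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D numeric array.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  RNifti::writeNifti(map, path)
  invisible(path)
}
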