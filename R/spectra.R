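#' Reference spectra for three-band SRS unmixing
#'
#' Constructs the 3x3 response matrix `S[band, component]` mapping
#' (protein, lipid, water) concentrations to intensities at the 2853, 2935 and
#' 3420 cm^-1 bands. Rows are bands, columns are components. The default
#' matrix is a diagonal-dominant stand-in for spectra measured from
#' calibration standards (BSA, DOPC, water): the 2853 cm^-1 (CH2) band is
#' lipid-dominant, 2935 cm^-1 (CH3) protein-dominant, and 3420 cm^-1 (OH)
#' water-dominant.
#'
#' @param matrix numeric 3x3 matrix of nonnegative responses; rows ordered
#'   (2853, 2935, 3420 cm^-1), columns ordered (protein, lipid, water).
#' @param source_labels free-text provenance of the spectra.
#' @param max_condition maximum acceptable 2-norm condition number; a matrix
#'   above this bound is refused because unmixing would be unstable.
#' @return An object of class `nori_spectra`.
#' @examples
#' sp <- nori_spectra()
#' sp$matrix %*% c(100, 50, 850)  # band intensities of one pixel
#' @export
nori_spectra <- function(matrix = NULL,
                         source_labels = "synthetic default (CH2/CH3/OH dominant)",
                         max_condition = 100) {
  if (is.null(matrix)) {
    matrix <- rbind(
      c(0.30, 1.00, 0.05),   # 2853 cm^-1, CH2: lipid-dominant
      c(1.00, 0.45, 0.10),   # 2935 cm^-1, CH3: protein-dominant
      c(0.05, 0.02, 1.00)    # 3420 cm^-1, OH : water-dominant
    )
  }
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(3L, 3L)))
    stop("reference spectra must be a 3x3 matrix", call. = FALSE)
  if (any(matrix < 0))
    stop("reference spectra entries must be nonnegative", call. = FALSE)
  dimnames(matrix) <- list(
    band = c("2853", "2935", "3420"),
    component = c("protein", "lipid", "water")
  )
  kappa <- kappa(matrix, exact = TRUE)
  if (!is.finite(kappa) || kappa > max_condition)
    stop(sprintf(
      "reference spectra condition number %.3g exceeds bound %.3g; unmixing refused",
      kappa, max_condition
    ), call. = FALSE)
  structure(
    list(matrix = matrix, source_labels = source_labels,
         condition_number = kappa),
    class = "nori_spectra"
  )
}

#' @export
print.nori_spectra <- function(x, ...) {
  cat("Reference spectra (bands x components), condition number",
      format(x$condition_number, digits = 4), "\n")
  print(x$matrix)
  cat("source:", x$source_labels, "\n")
  invisible(x)
}

#' Read / write reference spectra as YAML
#'
#' The sidecar format stores the 3x3 matrix with its band and component
#' labels plus the source description.
#'
#' @param spectra a [nori_spectra()] object.
#' @param path file path of the YAML document.
#' @return `write_spectra_yaml` returns `path` invisibly;
#'   `read_spectra_yaml` returns a `nori_spectra` object.
#' @export
write_spectra_yaml <- function(spectra, path) {
  stopifnot(inherits(spectra, "nori_spectra"))
  yaml::write_yaml(list(
    bands = rownames(spectra$matrix),
    components = colnames(spectra$matrix),
    matrix = lapply(seq_len(3), function(i) as.numeric(spectra$matrix[i, ])),
    source_labels = spectra$source_labels
  ), path)
  invisible(path)
}

#' @rdname write_spectra_yaml
#' @export
read_spectra_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(doc$matrix, as.numeric))
  nori_spectra(m, source_labels = doc$source_labels %||% "from file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
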