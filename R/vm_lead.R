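# Orthogonal X/Y/Z leads and the vector magnitude lead.
#
# The vector magnitude lead is the Euclidean norm of the orthogonal X, Y
# and Z leads, reconstructed from the 8 independent leads (I, II, V1-V6)
# by a fixed 3x8 linear transform.  The transform matrix is data, not
# code: any published 12-lead-to-XYZ matrix (Kors, inverse Dower,
# Guldenring, ...) can be supplied via `jt_config(vm = ...)` or a file in
# the same plain-text format as the bundled default.

#' Default 12-lead to XYZ transform matrix
#'
#' Reads the bundled plain-text coefficient table (the Kors regression
#' matrix; rows X, Y, Z; columns I, II, V1-V6).
#'
#' @param path optional path to an alternative coefficient file with the
#'   same layout (comment lines starting with `#`, then three
#'   whitespace-separated rows labelled X, Y, Z under a header of lead
#'   names).
#' @return A 3x8 numeric matrix with dimnames.
#' @export
default_xyz_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "xyz_transform_kors.txt", package = "jtpeak",
                        mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, row.names = 1, comment.char = "#")
  m <- as.matrix(tab)
  validate_xyz_matrix(m)
}

validate_xyz_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 8L)))
    jt_stop("jt_config_error", "XYZ transform must be a 3x8 matrix (rows X,Y,Z; columns I,II,V1-V6)")
  if (is.null(colnames(m))) colnames(m) <- REQUIRED_LEADS
  if (is.null(rownames(m))) rownames(m) <- c("X", "Y", "Z")
  missing <- setdiff(REQUIRED_LEADS, colnames(m))
  if (length(missing))
    jt_stop("jt_config_error",
            sprintf("transform matrix lacks column(s): %s", paste(missing, collapse = ", ")))
  m[, REQUIRED_LEADS, drop = FALSE]
}

#' Derive orthogonal X, Y, Z leads from a median beat
#'
#' Applies a fixed 3x8 linear transform to the 8 independent leads,
#' sample-wise.
#'
#' @param beat a [new_median_beat()] object containing leads I, II, V1-V6.
#' @param coefficients 3x8 matrix, or `NULL` for [default_xyz_matrix()].
#' @return Object of class `xyz_beat` with fields `x`, `y`, `z` (uV at
#'   1 kHz), `alignment_ms`, `median_rr_ms`.
#' @export
transform_xyz <- function(beat, coefficients = NULL) {
  stopifnot(inherits(beat, "median_beat"))
  if (is.null(coefficients)) coefficients <- default_xyz_matrix()
  m <- validate_xyz_matrix(coefficients)
  missing <- setdiff(REQUIRED_LEADS, beat$lead_names)
  if (length(missing))
    jt_stop("jt_format_error",
            sprintf("beat lacks required lead(s): %s", paste(missing, collapse = ", ")))
  xyz <- beat$samples[, REQUIRED_LEADS, drop = FALSE] %*% t(m)
  structure(
    list(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], fs = beat$fs,
         alignment_ms = beat$alignment_ms, median_rr_ms = beat$median_rr_ms),
    class = "xyz_beat"
  )
}

#' Vector magnitude lead
#'
#' `vm[t] = sqrt(x[t]^2 + y[t]^2 + z[t]^2)`; nonnegative by construction.
#'
#' @param xyz an `xyz_beat`.
#' @return Object of class `vm_beat` with fields `vm` (uV at 1 kHz),
#'   `alignment_ms`, `median_rr_ms`.
#' @export
vector_magnitude <- function(xyz) {
  stopifnot(inherits(xyz, "xyz_beat"))
  if (length(xyz$x) != length(xyz$y) || length(xyz$x) != length(xyz$z))
    jt_stop("jt_input_error", "x, y, z must have equal length")
  new_vm_beat(sqrt(xyz$x^2 + xyz$y^2 + xyz$z^2),
              alignment_ms = xyz$alignment_ms, median_rr_ms = xyz$median_rr_ms,
              fs = xyz$fs)
}

#' @rdname vector_magnitude
#' @param vm nonnegative amplitude series (uV) at 1 kHz.
#' @param alignment_ms,median_rr_ms beat timing metadata (ms).
#' @param fs sampling rate; must be 1000.
#' @export
new_vm_beat <- function(vm, alignment_ms, median_rr_ms, fs = 1000) {
  if (!is_finite_number(vm) || any(vm < 0))
    jt_stop("jt_input_error", "vector magnitude must be finite and nonnegative")
  if (fs != 1000)
    jt_stop("jt_input_error", "vm beats are defined at 1 kHz (1 ms resolution)")
  structure(
    list(vm = as.numeric(vm), fs = 1000, alignment_ms = alignment_ms,
         median_rr_ms = median_rr_ms),
    class = "vm_beat"
  )
}

#' @export
print.vm_beat <- function(x, ...) {
  cat(sprintf("<vm_beat> %d ms @ 1 kHz, alignment %g ms, median RR %.0f ms, peak %.0f uV\n",
              length(x$vm), x$alignment_ms, x$median_rr_ms, max(x$vm)))
  invisible(x)
}
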