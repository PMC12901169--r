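# JSON container for VOP sets.  Complex matrices are stored as paired
# real/imaginary 2-D arrays at full double precision, so a write/read
# round-trip reproduces the set bit for bit.

#' Write a VOP set to a JSON container
#'
#' The container schema is
#' `{format: "ptxsar-vop-json", schema_version: 1, n_channels, labels,`
#' `matrices: [{re: [[...]], im: [[...]]}, ...]}` — complex matrices as
#' paired real/imaginary arrays, serialized at full precision (the
#' round-trip is bit-exact).
#'
#' @param vops A [vop_set()].
#' @param path Output path (conventionally `.vops.json`).
#' @return `path`, invisibly.
#' @examples
#' v <- synth_vops(2, 2, rank = 2, seed = 1)
#' tf <- tempfile(fileext = ".vops.json")
#' write_vops(v, tf)
#' identical(read_vops(tf)$matrices, v$matrices)
#' @seealso [read_vops()]
#' @export
write_vops <- function(vops, path) {
  vops <- as_vop_set(vops)
  payload <- list(
    format = "ptxsar-vop-json",
    schema_version = 1L,
    n_channels = vops$n_channels,
    n_vops = vops$n_vops,
    labels = vops$labels,
    matrices = lapply(vops$matrices, function(Q) {
      list(re = Re(Q), im = Im(Q))
    }))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a VOP set from a JSON container
#'
#' Loads the container written by [write_vops()].  Shape mismatches, empty
#' sets and matrices that are non-Hermitian beyond
#' `ptxsar_tol("hermitian")` produce descriptive load failures.
#'
#' @param path Path to a `ptxsar-vop-json` file.
#' @return A [vop_set()].
#' @export
read_vops <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path),
          class = "ptxsar_bad_input")
  }
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "ptxsar-vop-json")) {
    abort(sprintf("'%s' is not a ptxsar VOP container.", basename(path)),
          class = "ptxsar_parse_error")
  }
  n <- as.integer(payload$n_channels)
  mats <- payload$matrices
  if (length(mats) == 0) {
    abort(sprintf("'%s' holds an empty VOP set.", basename(path)),
          class = "ptxsar_parse_error")
  }
  part <- function(rows, i, what) {
    if (length(rows) != n || any(lengths(rows) != n)) {
      abort(sprintf("'%s': %s part of VOP %d is not %d x %d.",
                    basename(path), what, i, n, n),
            class = "ptxsar_parse_error")
    }
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  matrices <- lapply(seq_along(mats), function(i) {
    re <- part(mats[[i]]$re, i, "real")
    im <- part(mats[[i]]$im, i, "imaginary")
    matrix(complex(real = re, imaginary = im), n, n)
  })
  labels <- unlist(payload$labels)
  if (length(labels) == 0) labels <- NULL
  vop_set(matrices, labels = labels)
}
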