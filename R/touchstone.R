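# Touchstone v1.1 (.sNp) reader/writer.  The port count comes from the file
# extension; RI/MA/DB formats and Hz/kHz/MHz/GHz option-line units are
# supported.  Touchstone v2.0 files are rejected outright rather than
# half-parsed.

touchstone_ports <- function(path) {
  m <- regmatches(path, regexpr("\\.s([0-9]+)p$", path, ignore.case = TRUE))
  if (length(m) == 0) {
    abort(sprintf("Cannot infer port count from '%s': expected a .sNp extension.",
                  basename(path)),
          class = "ptxsar_parse_error")
  }
  as.integer(sub("\\.s([0-9]+)p$", "\\1", m, ignore.case = TRUE))
}

parse_error <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", basename(path), line, msg),
        class = "ptxsar_parse_error")
}

#' Read an S-parameter matrix from a Touchstone v1.1 file
#'
#' Parses a `.sNp` file (port count `N` taken from the extension), handling
#' the `RI`, `MA` and `DB` number formats and all option-line frequency
#' units.  When the file holds several frequency points, the point nearest
#' `frequency_hz` is selected; without a requested frequency a
#' multi-frequency file is an error that lists the available frequencies.
#' Touchstone v2.0 files (`[Version]` keyword) are rejected.
#'
#' The two-port data ordering quirk of the standard (S11 S21 S12 S22) is
#' honoured; larger matrices are read row-major.
#'
#' @param path Path to the Touchstone file.
#' @param frequency_hz Optional frequency in Hz to select.
#' @return An [smatrix()] carrying the selected frequency and the reference
#'   impedance as attribute `"z0_ohm"`.
#' @examples
#' tf <- tempfile(fileext = ".s1p")
#' writeLines(c("# MHz S RI R 50", "297.2 0.1 -0.2"), tf)
#' read_touchstone(tf)$values
#' @seealso [write_touchstone()]
#' @export
read_touchstone <- function(path, frequency_hz = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path),
          class = "ptxsar_bad_input")
  }
  n <- touchstone_ports(path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*\\[Version\\]", lines, ignore.case = TRUE))) {
    abort(sprintf(
      "'%s' is a Touchstone v2.0 file; only v1.1 is supported.",
      basename(path)), class = "ptxsar_parse_error")
  }
  # strip comments, keep line numbers
  stripped <- sub("!.*$", "", lines)
  opt <- list(unit = 1e9, format = "MA", z0 = 50)   # v1.1 defaults
  seen_option <- FALSE
  tokens <- numeric(0)
  token_line <- integer(0)
  units <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
  for (i in seq_along(stripped)) {
    txt <- trimws(stripped[i])
    if (!nzchar(txt)) next
    if (startsWith(txt, "#")) {
      if (seen_option) next                         # later option lines ignored
      seen_option <- TRUE
      parts <- toupper(strsplit(trimws(sub("^#", "", txt)), "\\s+")[[1]])
      parts <- parts[nzchar(parts)]
      j <- 1
      while (j <= length(parts)) {
        p <- parts[j]
        if (p %in% names(units)) {
          opt$unit <- units[[p]]
        } else if (p %in% c("RI", "MA", "DB")) {
          opt$format <- p
        } else if (p == "S") {
          # scattering parameters, the only supported type
        } else if (p %in% c("Y", "Z", "H", "G")) {
          parse_error(path, i, sprintf(
            "parameter type '%s' is not supported (only S).", p))
        } else if (p == "R") {
          if (j == length(parts) ||
              is.na(suppressWarnings(as.numeric(parts[j + 1])))) {
            parse_error(path, i, "malformed option line: 'R' without a value.")
          }
          opt$z0 <- as.numeric(parts[j + 1])
          j <- j + 1
        } else {
          parse_error(path, i, sprintf(
            "malformed option line: unknown token '%s'.", p))
        }
        j <- j + 1
      }
      next
    }
    toks <- strsplit(txt, "[[:space:],]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      parse_error(path, i, "non-numeric token in data line.")
    }
    tokens <- c(tokens, vals)
    token_line <- c(token_line, rep(i, length(vals)))
  }
  per_point <- 1 + 2 * n^2
  if (length(tokens) == 0) {
    abort(sprintf("'%s' contains no data.", basename(path)),
          class = "ptxsar_parse_error")
  }
  if (length(tokens) %% per_point != 0) {
    parse_error(path, token_line[length(token_line)], sprintf(
      paste0("inconsistent column count: %d values is not a multiple of the ",
             "%d values per frequency point of a %d-port file."),
      length(tokens), per_point, n))
  }
  n_points <- length(tokens) %/% per_point
  block <- matrix(tokens, nrow = per_point)
  freqs <- block[1, ] * opt$unit
  pick <- 1L
  if (n_points > 1) {
    if (is.null(frequency_hz)) {
      abort(sprintf(
        paste0("'%s' holds %d frequency points; request one via ",
               "`frequency_hz`. Available: %s Hz."),
        basename(path), n_points,
        paste(format(freqs, trim = TRUE), collapse = ", ")),
        class = "ptxsar_parse_error")
    }
    pick <- which.min(abs(freqs - frequency_hz))
  }
  raw <- block[-1, pick]
  pairs <- matrix(raw, ncol = 2, byrow = TRUE)
  vals <- switch(opt$format,
    RI = complex(real = pairs[, 1], imaginary = pairs[, 2]),
    MA = pairs[, 1] * exp(1i * pairs[, 2] * pi / 180),
    DB = 10^(pairs[, 1] / 20) * exp(1i * pairs[, 2] * pi / 180))
  S <- if (n == 2) {
    matrix(vals, 2, 2)          # column fill matches S11 S21 S12 S22
  } else {
    matrix(vals, n, n, byrow = TRUE)
  }
  out <- smatrix(S, frequency_hz = freqs[pick],
                 label = basename(path))
  attr(out, "z0_ohm") <- opt$z0
  out
}

#' Write an S-matrix to a Touchstone v1.1 file
#'
#' Writes a single-frequency `.sNp` file in `RI` format with a GHz option
#' line (reference impedance 50 Ohm), using the standard two-port ordering
#' and at most four complex pairs per line for larger matrices.
#'
#' @param S An [smatrix()].
#' @param path Output path; its `.sNp` extension must match the channel
#'   count.
#' @return `path`, invisibly.
#' @examples
#' S <- smatrix(matrix(0.2 + 0i, 1, 1), frequency_hz = 297.2e6)
#' tf <- tempfile(fileext = ".s1p")
#' write_touchstone(S, tf)
#' read_touchstone(tf)$values
#' @export
write_touchstone <- function(S, path) {
  S <- as_smatrix(S)
  n <- S$n_channels
  if (touchstone_ports(path) != n) {
    abort(sprintf("'%s' implies %d ports but the S-matrix has %d channels.",
                  basename(path), touchstone_ports(path), n),
          class = "ptxsar_bad_input")
  }
  freq_ghz <- (S$frequency_hz %||% 1e9) / 1e9
  fmt <- function(x) sprintf("%.17g %.17g", Re(x), Im(x))
  lines <- c(sprintf("! ptxsar export%s",
                     if (is.null(S$label)) "" else paste0(": ", S$label)),
             "# GHz S RI R 50")
  V <- S$values
  if (n == 1) {
    lines <- c(lines, sprintf("%.17g %s", freq_ghz, fmt(V[1, 1])))
  } else if (n == 2) {
    lines <- c(lines, sprintf("%.17g %s %s %s %s", freq_ghz,
                              fmt(V[1, 1]), fmt(V[2, 1]),
                              fmt(V[1, 2]), fmt(V[2, 2])))
  } else {
    for (i in seq_len(n)) {
      row <- vapply(seq_len(n), function(j) fmt(V[i, j]), character(1))
      chunks <- split(row, ceiling(seq_along(row) / 4))
      for (ci in seq_along(chunks)) {
        prefix <- if (i == 1 && ci == 1) sprintf("%.17g ", freq_ghz) else "  "
        lines <- c(lines, paste0(prefix, paste(chunks[[ci]], collapse = " ")))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
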