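#' Acquisition schemes for combined T2*-diffusion MRI
#'
#' An acquisition scheme is a tibble with one row per acquired volume and
#' columns `te` (echo time, seconds), `b` (b-value, s/mm^2) and `gx`, `gy`,
#' `gz` (diffusion gradient direction; the zero vector is used for b = 0).
#' The shortest echo time `te_min` anchors the signal model: the predicted
#' signal at (`te_min`, b = 0) equals the proton-density scale S0, and the
#' first b = 0 volume at `te_min` is the conventional reference for mask
#' drawing.
#'
#' @name dr_scheme
#' @keywords internal
NULL

new_dr_scheme <- function(df) {
  df <- tibble::as_tibble(df)
  structure(df, class = c("dr_scheme", class(df)))
}

#' Validate an acquisition scheme
#'
#' Checks the scheme invariants: positive echo times, non-negative b-values,
#' unit gradient directions wherever b > 0, and the presence of at least one
#' b = 0 volume at the shortest echo time.
#'
#' @param scheme A scheme tibble with columns `te`, `b`, `gx`, `gy`, `gz`.
#' @param tol Tolerance on |direction| - 1 for diffusion-weighted rows.
#' @return The validated scheme, invisibly classed as `dr_scheme`.
#' @export
validate_scheme <- function(scheme, tol = 1e-6) {
  required <- c("te", "b", "gx", "gy", "gz")
  missing <- setdiff(required, names(scheme))
  if (length(missing) > 0) {
    stop("scheme is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(scheme) == 0) stop("scheme has no measurements")
  if (any(!is.finite(scheme$te)) || any(scheme$te <= 0)) {
    stop("echo times must be finite and > 0 (seconds)")
  }
  if (any(!is.finite(scheme$b)) || any(scheme$b < 0)) {
    stop("b-values must be finite and >= 0")
  }
  norms <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  dw <- scheme$b > 0
  if (any(abs(norms[dw] - 1) > tol)) {
    stop("gradient directions must be unit vectors where b > 0")
  }
  tmin <- min(scheme$te)
  if (!any(scheme$b == 0 & scheme$te == tmin)) {
    stop("scheme must contain a b = 0 measurement at the shortest echo time")
  }
  invisible(new_dr_scheme(scheme))
}

#' Shortest echo time of a scheme
#'
#' @param scheme An acquisition scheme.
#' @return The minimum echo time in seconds.
#' @export
te_min <- function(scheme) min(scheme$te)

# Deterministic, approximately uniform unit vectors (Fibonacci sphere).
fibonacci_directions <- function(n) {
  if (n == 1) return(matrix(c(0, 0, 1), nrow = 1))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Default combined T2*-diffusion (ZEBRA-style) acquisition scheme
#'
#' Builds the multi-echo multi-b-value encoding used throughout the package:
#' four echo times (78, 114, 150, 186 ms), each crossed with a diffusion list
#' of one b = 0 volume, ten b-values (5, 10, 25, 50, 100, 200, 400, 600, 1200,
#' 1600 s/mm^2) at 3 directions each, b = 18 at 8 directions, b = 36 at 7
#' directions and b = 800 at 15 directions -- 61 diffusion volumes per echo
#' time, 244 measurements in total. `"reduced_test"` returns a documented
#' small subset (4 echo times x b in {0, 36, 200, 1600}, 16 measurements)
#' intended for fast tests and examples.
#'
#' @param crossing_mode `"full_cross"` (default) or `"reduced_test"`.
#' @return A `dr_scheme` tibble (echo times in seconds).
#' @examples
#' sch <- zebra_scheme("reduced_test")
#' nrow(sch)
#' te_min(sch)
#' @export
zebra_scheme <- function(crossing_mode = c("full_cross", "reduced_test")) {
  crossing_mode <- match.arg(crossing_mode)
  te_ms <- c(78, 114, 150, 186)
  if (crossing_mode == "full_cross") {
    multi_b <- c(5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600)
    shells <- list(list(b = 0, n = 1))
    for (b in multi_b) shells <- c(shells, list(list(b = b, n = 3)))
    shells <- c(shells, list(
      list(b = 18, n = 8), list(b = 36, n = 7), list(b = 800, n = 15)
    ))
  } else {
    shells <- list(
      list(b = 0, n = 1), list(b = 36, n = 1),
      list(b = 200, n = 1), list(b = 1600, n = 1)
    )
  }
  rows <- purrr::map_dfr(shells, function(sh) {
    if (sh$b == 0) {
      tibble::tibble(b = 0, gx = 0, gy = 0, gz = 0)
    } else {
      g <- fibonacci_directions(sh$n)
      tibble::tibble(b = sh$b, gx = g[, 1], gy = g[, 2], gz = g[, 3])
    }
  })
  scheme <- tidyr::crossing(te = te_ms / 1000, rows) |>
    dplyr::arrange(.data$te) |>
    dplyr::select("te", "b", "gx", "gy", "gz")
  validate_scheme(scheme)
  new_dr_scheme(scheme)
}

#' Read / write an acquisition scheme
#'
#' Schemes are stored as whitespace- or comma-delimited text with header
#' columns `te_ms`, `b`, `gx`, `gy`, `gz`; echo times are converted from
#' milliseconds to seconds on load, so a save/load round trip reproduces the
#' in-memory scheme exactly.
#'
#' @param path Path to a delimited text file.
#' @return `read_scheme()` returns a validated `dr_scheme` tibble.
#' @export
read_scheme <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#", check.names = TRUE)
  if (ncol(df) == 1) {  # comma-delimited fallback
    df <- utils::read.csv(path, comment.char = "#")
  }
  required <- c("te_ms", "b", "gx", "gy", "gz")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("scheme file is missing columns: ", paste(missing, collapse = ", "))
  }
  scheme <- tibble::tibble(
    te = df$te_ms / 1000, b = df$b,
    gx = df$gx, gy = df$gy, gz = df$gz
  )
  validate_scheme(scheme)
  new_dr_scheme(scheme)
}

#' @param scheme A `dr_scheme` (or compatible tibble).
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  out <- data.frame(
    te_ms = scheme$te * 1000, b = scheme$b,
    gx = scheme$gx, gy = scheme$gy, gz = scheme$gz
  )
  utils::write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
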