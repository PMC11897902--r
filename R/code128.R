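# Code128 symbology: encoder for the fixture renderer and a run-length
# decoder for the side-view pipeline. Patterns are the standard module
# widths (bar,space,bar,space,bar,space), 11 modules per symbol; the
# stop pattern 2331112 has 13 modules and a trailing bar.

CODE128_PATTERNS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232")
CODE128_STOP <- "2331112"
CODE128_START_B <- 104L
CODE128_START_C <- 105L

code128_widths <- function(value) {
  as.integer(strsplit(CODE128_PATTERNS[value + 1L], "")[[1]])
}

#' Encode a payload as a Code128 module sequence
#'
#' Uses code set B (printable ASCII 32-126), which covers the sample
#' identifiers used on tube labels. Returns the bar/space module vector
#' including start symbol, data, checksum and stop, without quiet
#' zones.
#'
#' @param payload character scalar, ASCII 32-126.
#' @return integer vector of 0/1 modules (1 = bar/ink).
#' @export
code128_encode <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1L,
            nchar(payload) >= 1L)
  vals <- utf8ToInt(payload) - 32L
  if (any(vals < 0L | vals > 94L))
    stop("payload contains characters outside Code128 set B")
  checksum <- (CODE128_START_B +
               sum(vals * seq_along(vals))) %% 103L
  widths <- unlist(lapply(c(CODE128_START_B, vals, checksum),
                          code128_widths))
  widths <- c(widths, as.integer(strsplit(CODE128_STOP, "")[[1]]))
  # runs alternate bar/space starting and (after the stop) ending on a bar
  vals01 <- rep(rep_len(c(1L, 0L), length(widths)), widths)
  vals01
}

# Decode one scanline already reduced to alternating run lengths that
# start and end on a bar. Returns the payload string or NULL.
code128_decode_runs <- function(runs) {
  n <- length(runs)
  if (n < 25L || (n - 7L) %% 6L != 0L) return(NULL)
  n_sym <- (n - 7L) %/% 6L
  pat_lookup <- stats::setNames(0:105, CODE128_PATTERNS)
  read_symbol <- function(r, total) {
    w <- sum(r) / total
    d <- pmin(pmax(round(r / w), 1L), 4L)
    if (sum(d) != total) return(NA_integer_)
    key <- paste(d, collapse = "")
    if (total == 13L) return(if (key == CODE128_STOP) -1L else NA_integer_)
    v <- pat_lookup[key]
    if (is.na(v)) NA_integer_ else unname(v)
  }
  syms <- integer(n_sym)
  for (k in seq_len(n_sym)) {
    v <- read_symbol(runs[(6L * (k - 1L) + 1L):(6L * k)], 11L)
    if (is.na(v)) return(NULL)
    syms[k] <- v
  }
  if (is.na(read_symbol(runs[(n - 6L):n], 13L))) return(NULL)
  if (!syms[1] %in% 103:105) return(NULL)
  data <- syms[2:(n_sym - 1L)]
  check <- syms[n_sym]
  if (((syms[1] + sum(data * seq_along(data))) %% 103L) != check)
    return(NULL)
  code128_translate(syms[1], data)
}

# Translate start symbol + data values to text across code sets A/B/C.
code128_translate <- function(start, data) {
  set <- c(`103` = "A", `104` = "B", `105` = "C")[[as.character(start)]]
  out <- character(0)
  shift <- NULL
  for (v in data) {
    cur <- if (!is.null(shift)) shift else set
    shift <- NULL
    if (cur == "C") {
      if (v <= 99L) { out <- c(out, sprintf("%02d", v)); next }
      if (v == 100L) { set <- "B"; next }
      if (v == 101L) { set <- "A"; next }
      next                                   # FNC1
    }
    if (cur == "B") {
      if (v <= 94L) { out <- c(out, intToUtf8(v + 32L)); next }
      if (v == 98L) { shift <- "A"; next }
      if (v == 99L) { set <- "C"; next }
      if (v == 101L) { set <- "A"; next }
      next
    }
    # set A
    if (v <= 63L) { out <- c(out, intToUtf8(v + 32L)); next }
    if (v <= 95L) { out <- c(out, intToUtf8(v - 64L)); next }
    if (v == 98L) { shift <- "B"; next }
    if (v == 99L) { set <- "C"; next }
    if (v == 100L) { set <- "B"; next }
  }
  paste(out, collapse = "")
}

# Attempt to decode a single binary scanline (1 = ink). Trims quiet
# zones, tries both reading directions.
code128_decode_line <- function(line) {
  if (!any(line == 1L)) return(NULL)
  r <- rle(as.integer(line))
  # trim leading/trailing space runs
  if (r$values[1] == 0L) {
    r$values <- r$values[-1]; r$lengths <- r$lengths[-1]
  }
  n <- length(r$values)
  if (n > 0L && r$values[n] == 0L) {
    r$values <- r$values[-n]; r$lengths <- r$lengths[-n]
  }
  if (length(r$values) == 0L) return(NULL)
  runs <- r$lengths
  out <- code128_decode_runs(runs)
  if (!is.null(out)) return(out)
  code128_decode_runs(rev(runs))
}
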