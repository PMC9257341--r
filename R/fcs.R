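# Minimal FCS 3.0 list-mode writer/reader: float32 data, little-endian,
# one event per cell, one parameter per numeric column. Covers exactly the
# subset of the standard needed to exchange per-cell marker fractions.

#' Write a numeric data.frame as an FCS 3.0 file
#'
#' @param df data.frame of numeric columns; one event per row, one
#'   parameter per column (parameter short names = column names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(df, path) {
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("all columns must be numeric")
  }
  p <- ncol(df); n <- nrow(df)
  if (p < 1L) stop("need at least one parameter")
  delim <- "/"
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p)
  )
  for (j in seq_len(p)) {
    rng <- if (n) max(abs(df[[j]]), 1) else 1
    kw[sprintf("$P%dN", j)] <- gsub(delim, "_", names(df)[j], fixed = TRUE)
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(ceiling(rng), scientific = FALSE)
  }
  text_of <- function(bd, ed) {
    k <- kw
    k["$BEGINDATA"] <- sprintf("%10d", bd)
    k["$ENDDATA"] <- sprintf("%10d", ed)
    paste0(delim, paste0(names(k), delim, unname(k), delim, collapse = ""))
  }
  header_len <- 58L
  txt0 <- text_of(0L, 0L)
  text_begin <- header_len
  text_end <- text_begin + nchar(txt0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_len <- 4L * n * p
  data_end <- if (data_len) data_begin + data_len - 1L else 0L
  txt <- text_of(if (data_len) data_begin else 0L, data_end)
  stopifnot(nchar(txt, type = "bytes") == nchar(txt0, type = "bytes"))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_len) data_begin else 0L, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  if (data_len) {
    ev <- as.numeric(t(as.matrix(df)))  # row-major: event-interleaved
    writeBin(ev, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an FCS file written by [write_fcs()]
#'
#' Parses the TEXT segment and reads the float data matrix. Supports
#' list-mode float32 files with a uniform byte order.
#'
#' @param path FCS file path.
#' @return data.frame with one column per parameter.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0") stop("not an FCS 3.0 file")
  offs <- as.integer(substring(header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text_begin <- offs[1]; text_end <- offs[2]
  seek(con, text_begin)
  txt <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, keys)
  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L") {
    stop("only list-mode float FCS is supported")
  }
  endian <- if (kw[["$BYTEORD"]] == "4,3,2,1") "big" else "little"
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  nm <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]], character(1))
  if (n * p > 0) {
    seek(con, as.integer(kw[["$BEGINDATA"]]))
    v <- readBin(con, "numeric", n = n * p, size = 4L, endian = endian)
    m <- matrix(v, nrow = n, ncol = p, byrow = TRUE)
  } else {
    m <- matrix(numeric(), 0, p)
  }
  df <- as.data.frame(m)
  names(df) <- nm
  df
}
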