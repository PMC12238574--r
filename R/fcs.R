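# Minimal FCS 3.1 support: float32 list-mode data, linear values only.
# Covers what a cytometry pipeline needs to round-trip its own event data
# (and to ingest plain float FCS exports); no log-amplifier transforms, no
# analysis segment, no multi-dataset files.

.FCS_DELIM <- "/"

# keyword values must not contain the delimiter (no escaping implemented)
.fcsText <- function(kv) {
  stopifnot(!any(grepl(.FCS_DELIM, c(names(kv), unlist(kv)), fixed = TRUE)))
  paste0(.FCS_DELIM,
         paste0(names(kv), .FCS_DELIM, unlist(kv), .FCS_DELIM, collapse = ""))
}

.writeFCS <- function(path, mat, keywords = character()) {
  stopifnot(is.matrix(mat), is.numeric(mat), ncol(mat) >= 1)
  n <- nrow(mat); p <- ncol(mat)
  pn <- colnames(mat)
  if (is.null(pn)) pn <- paste0("P", seq_len(p))

  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    # fixed-width placeholders keep the TEXT length stable
    "$BEGINDATA" = "0000000000", "$ENDDATA" = "0000000000",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p))
  for (j in seq_len(p)) {
    kv[[sprintf("$P%dN", j)]] <- pn[j]
    kv[[sprintf("$P%dB", j)]] <- "32"
    kv[[sprintf("$P%dE", j)]] <- "0,0"
    kv[[sprintf("$P%dR", j)]] <- format(max(262144, 2^ceiling(log2(
      max(1, max(mat[, j], na.rm = TRUE))))), scientific = FALSE)
  }
  if (length(keywords)) kv[names(keywords)] <- unname(keywords)

  text_begin <- 58L
  text_len <- nchar(.fcsText(kv), type = "bytes")
  data_begin <- text_begin + text_len
  data_end <- data_begin + 4L * n * p - 1L
  kv[["$BEGINDATA"]] <- sprintf("%010d", data_begin)
  kv[["$ENDDATA"]] <- sprintf("%010d", data_end)
  text <- .fcsText(kv)
  stopifnot(nchar(text, type = "bytes") == text_len)

  off <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   off(text_begin), off(text_begin + text_len - 1L),
                   off(data_begin), off(data_end),
                   off(0L), off(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

.readFCS <- function(path) {
  size <- file.info(path)$size
  raw <- readBin(path, "raw", n = size)
  header <- rawToChar(raw[1:58])
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version or not an FCS file: ", version)
  seg <- function(i) {
    as.integer(trimws(substr(header, 11 + 8 * (i - 1), 10 + 8 * i)))
  }
  text_begin <- seg(1); text_end <- seg(2)
  data_begin <- seg(3); data_end <- seg(4)

  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- as.list(parts[seq(2, length(parts), by = 2)])
  names(kw) <- parts[seq(1, length(parts), by = 2)]

  getkw <- function(name, default = NULL) {
    hit <- kw[[name]]
    if (is.null(hit)) default else hit
  }
  if (is.na(data_begin) || data_begin == 0L)
    data_begin <- as.integer(getkw("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0L)
    data_end <- as.integer(getkw("$ENDDATA"))
  dtype <- getkw("$DATATYPE")
  if (!identical(dtype, "F"))
    stop("only float32 ($DATATYPE F) FCS data are supported; got ", dtype)
  p <- as.integer(getkw("$PAR"))
  n <- as.integer(getkw("$TOT"))
  byteord <- getkw("$BYTEORD", "1,2,3,4")
  endian <- if (substr(byteord, 1, 1) == "1") "little" else "big"
  for (j in seq_len(p)) {
    b <- getkw(sprintf("$P%dB", j), "32")
    if (!identical(b, "32"))
      stop("parameter ", j, " is not 32-bit float ($PnB = ", b, ")")
  }
  vals <- readBin(raw[(data_begin + 1):(data_end + 1)], "numeric",
                  n = n * p, size = 4L, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(p), function(j)
    getkw(sprintf("$P%dN", j), paste0("P", j)), character(1))
  list(data = mat, keywords = kw)
}
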