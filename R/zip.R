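# Minimal ZIP writer (store method, no compression) used for the results
# bundle. Entries are written with fixed DOS timestamps so identical inputs
# give byte-identical archives; base R's unz() reads them back.

crc32_lookup <- local({
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(crc32_lookup[idx + 1L], bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int_le <- function(x, size) {
  # little-endian raw encoding of a (possibly 32-bit-patterned) integer
  writeBin(as.integer(x), raw(), size = size, endian = "little")[seq_len(size)]
}

#' Write a ZIP archive of in-memory entries
#'
#' Entries are stored uncompressed with fixed timestamps, which keeps
#' archives deterministic. Character content is encoded as-is; raw vectors
#' are written verbatim.
#'
#' @param path Output archive path.
#' @param entries Named list: entry name -> character (concatenated with
#'   newlines, trailing newline added) or raw vector.
#' @return Invisibly, `path`.
#' @export
write_zip <- function(path, entries) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop_validation("zip entries must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  dos_date <- int_le(bitwOr(bitwShiftL(2020L - 1980L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L)), 2)
  dos_time <- int_le(0L, 2)
  centrals <- list()
  offset <- 0L
  for (nm in names(entries)) {
    data <- entries[[nm]]
    if (is.character(data)) data <- charToRaw(paste0(paste(data, collapse = "\n"), "\n"))
    name_raw <- charToRaw(nm)
    crc <- crc32(data)
    sz <- length(data)
    local_hdr <- c(charToRaw("PK\x03\x04"), int_le(20L, 2), int_le(0L, 2),
                   int_le(0L, 2), dos_time, dos_date, int_le(crc, 4),
                   int_le(sz, 4), int_le(sz, 4), int_le(length(name_raw), 2),
                   int_le(0L, 2), name_raw)
    writeBin(local_hdr, con)
    writeBin(data, con)
    centrals[[nm]] <- c(charToRaw("PK\x01\x02"), int_le(20L, 2), int_le(20L, 2),
                        int_le(0L, 2), int_le(0L, 2), dos_time, dos_date,
                        int_le(crc, 4), int_le(sz, 4), int_le(sz, 4),
                        int_le(length(name_raw), 2), int_le(0L, 2), int_le(0L, 2),
                        int_le(0L, 2), int_le(0L, 2), int_le(0L, 4),
                        int_le(offset, 4), name_raw)
    offset <- offset + length(local_hdr) + sz
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  end <- c(charToRaw("PK\x05\x06"), int_le(0L, 2), int_le(0L, 2),
           int_le(length(entries), 2), int_le(length(entries), 2),
           int_le(length(cd), 4), int_le(offset, 4), int_le(0L, 2))
  writeBin(end, con)
  invisible(path)
}
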