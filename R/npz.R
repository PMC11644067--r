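# Minimal npy/npz container support.
#
# No package in this R installation reads or writes numpy's .npy format or
# the .npz archive (a ZIP of .npy members), and no external zip binary is
# available, so both are implemented here: npy v1.0 with '<f8' / '<i4'
# (write) and '<f8', '<f4', '<i8', '<i4', '<i2', '|u1', '|i1' (read);
# ZIP with stored members on write, stored or deflated members on read
# (deflated streams are inflated by wrapping them in a gzip frame for
# memDecompress). Array data crosses the row-major/column-major boundary via
# aperm, so shapes and element order match numpy exactly.

# ---- little-endian byte helpers ---------------------------------------------

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32_raw <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
raw_u16 <- function(r) as.double(r[1]) + 256 * as.double(r[2])
raw_u32 <- function(r) {
  as.double(r[1]) + 256 * as.double(r[2]) + 65536 * as.double(r[3]) +
    16777216 * as.double(r[4])
}

# ---- CRC32 (pure R, table-driven) -------------------------------------------

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- integer(256)
    for (i in 0:255) {
      cr <- i
      for (j in 1:8) {
        cr <- if (bitwAnd(cr, 1L) != 0L) {
          bitwXor(bitwShiftR(cr, 1L), -306674912L)  # 0xEDB88320
        } else bitwShiftR(cr, 1L)
      }
      tab[i + 1L] <- cr
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  cr <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    cr <- bitwXor(bitwShiftR(cr, 8L), tab[bitwAnd(bitwXor(cr, b[i]), 255L) + 1L])
  }
  cr <- bitwXor(cr, -1L)
  if (cr < 0) cr + 4294967296 else as.double(cr)
}

# ---- npy --------------------------------------------------------------------

npy_serialize <- function(arr) {
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  shp <- dim(arr)
  shape_str <- if (length(shp) == 1L) paste0("(", shp, ",)") else
    paste0("(", paste(shp, collapse = ", "), ")")
  if (is.integer(arr)) {
    descr <- "<i4"; size <- 4L
  } else {
    descr <- "<f8"; size <- 8L
    storage.mode(arr) <- "double"
  }
  header <- paste0("{'descr': '", descr, "', 'fortran_order': False, 'shape': ",
                   shape_str, ", }")
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  # row-major element order
  rowmajor <- if (length(shp) > 1L) aperm(arr, rev(seq_along(shp))) else arr
  c(
    as.raw(c(0x93)), charToRaw("NUMPY"), as.raw(c(1L, 0L)),
    u16_raw(nchar(header)),
    charToRaw(header),
    writeBin(as.vector(rowmajor), raw(), size = size, endian = "little")
  )
}

npy_parse <- function(bytes) {
  if (!identical(bytes[1:6], c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an npy member")
  }
  ver <- as.integer(bytes[7])
  if (ver == 1L) {
    hlen <- raw_u16(bytes[9:10]); off <- 10L
  } else {
    hlen <- raw_u32(bytes[9:12]); off <- 12L
  }
  header <- rawToChar(bytes[(off + 1L):(off + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shp <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shp) == 0L || any(is.na(shp))) shp <- integer(0)
  data_raw <- bytes[(off + hlen + 1L):length(bytes)]
  n <- if (length(shp)) prod(shp) else 1L
  vals <- switch(descr,
    "<f8" = readBin(data_raw, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(data_raw, "double", n, size = 4, endian = "little"),
    "<i4" = readBin(data_raw, "integer", n, size = 4, endian = "little"),
    "<i2" = readBin(data_raw, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "|u1" = readBin(data_raw, "integer", n, size = 1, signed = FALSE),
    "|i1" = readBin(data_raw, "integer", n, size = 1, signed = TRUE),
    "<i8" = {
      lo <- readBin(data_raw, "integer", 2L * n, size = 4, endian = "little")
      even <- seq(1L, 2L * n, by = 2L)
      lo_u <- as.double(lo[even]); lo_u[lo_u < 0] <- lo_u[lo_u < 0] + 4294967296
      hi <- as.double(lo[even + 1L])
      v <- hi * 4294967296 + lo_u
      if (all(abs(v) < 2^31)) as.integer(v) else v
    },
    stop("unsupported npy dtype: ", descr)
  )
  if (length(shp) <= 1L) return(vals)
  if (fortran) {
    array(vals, dim = shp)
  } else {
    aperm(array(vals, dim = rev(shp)), rev(seq_along(shp)))
  }
}

# ---- zip container ----------------------------------------------------------

#' Write named arrays to an npz-layout archive
#' @param arrays named list of numeric/integer arrays.
#' @param path output path.
#' @keywords internal
npz_write <- function(arrays, path) {
  stopifnot(length(names(arrays)) == length(arrays), all(nzchar(names(arrays))))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(arrays))
  entries <- list()
  pos <- 0
  for (i in seq_along(arrays)) {
    name <- paste0(names(arrays)[i], ".npy")
    data <- npy_serialize(arrays[[i]])
    crc <- crc32(data)
    nm <- charToRaw(name)
    local_hdr <- c(u32_raw(0x04034b50), u16_raw(20), u16_raw(0), u16_raw(0),
                   u16_raw(0), u16_raw(0), u32_raw(crc),
                   u32_raw(length(data)), u32_raw(length(data)),
                   u16_raw(length(nm)), u16_raw(0))
    offsets[i] <- pos
    writeBin(c(local_hdr, nm, data), con)
    pos <- pos + length(local_hdr) + length(nm) + length(data)
    entries[[i]] <- list(name = nm, crc = crc, size = length(data))
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    cd <- c(u32_raw(0x02014b50), u16_raw(20), u16_raw(20), u16_raw(0),
            u16_raw(0), u16_raw(0), u16_raw(0), u32_raw(e$crc),
            u32_raw(e$size), u32_raw(e$size), u16_raw(length(e$name)),
            u16_raw(0), u16_raw(0), u16_raw(0), u16_raw(0), u32_raw(0),
            u32_raw(offsets[i]))
    writeBin(c(cd, e$name), con)
    cd_len <- cd_len + length(cd) + length(e$name)
  }
  eocd <- c(u32_raw(0x06054b50), u16_raw(0), u16_raw(0),
            u16_raw(length(entries)), u16_raw(length(entries)),
            u32_raw(cd_len), u32_raw(cd_start), u16_raw(0))
  writeBin(eocd, con)
  invisible(path)
}

inflate_raw <- function(comp, crc, usize) {
  gz <- c(as.raw(c(0x1f, 0x8b, 0x08, 0x00, 0, 0, 0, 0, 0x00, 0x03)),
          comp, u32_raw(crc), u32_raw(usize %% 4294967296))
  memDecompress(gz, type = "gzip")
}

#' Read all arrays from an npz-layout archive
#' @param path archive path.
#' @return named list of arrays.
#' @keywords internal
npz_read <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  out <- list()
  pos <- 1L
  repeat {
    if (pos + 3L > length(bytes)) break
    sig <- raw_u32(bytes[pos:(pos + 3L)])
    if (sig != 0x04034b50) break
    flags <- raw_u16(bytes[(pos + 6L):(pos + 7L)])
    method <- raw_u16(bytes[(pos + 8L):(pos + 9L)])
    crc <- raw_u32(bytes[(pos + 14L):(pos + 17L)])
    csize <- raw_u32(bytes[(pos + 18L):(pos + 21L)])
    usize <- raw_u32(bytes[(pos + 22L):(pos + 25L)])
    nlen <- raw_u16(bytes[(pos + 26L):(pos + 27L)])
    xlen <- raw_u16(bytes[(pos + 28L):(pos + 29L)])
    name <- rawToChar(bytes[(pos + 30L):(pos + 29L + nlen)])
    # zip64: 0xFFFFFFFF sizes are placeholders; real values sit in extra field 1
    if ((usize == 4294967295 || csize == 4294967295) && xlen > 0) {
      ex <- bytes[(pos + 30L + nlen):(pos + 29L + nlen + xlen)]
      ep <- 1L
      raw_u64 <- function(r) sum(as.double(r) * 256^(0:7))
      while (ep + 3L <= length(ex)) {
        eid <- raw_u16(ex[ep:(ep + 1L)])
        esz <- raw_u16(ex[(ep + 2L):(ep + 3L)])
        if (eid == 1L) {
          fp <- ep + 4L
          if (usize == 4294967295) {
            usize <- raw_u64(ex[fp:(fp + 7L)]); fp <- fp + 8L
          }
          if (csize == 4294967295) csize <- raw_u64(ex[fp:(fp + 7L)])
          break
        }
        ep <- ep + 4L + esz
      }
    }
    dstart <- pos + 30L + nlen + xlen
    if (bitwAnd(flags, 8L) != 0L && csize == 0) {
      stop("npz member '", name, "' uses a streaming data descriptor; unsupported")
    }
    comp <- bytes[dstart:(dstart + csize - 1L)]
    data <- if (method == 0) comp
            else if (method == 8) inflate_raw(comp, crc, usize)
            else stop("unsupported zip compression method ", method)
    out[[sub("\\.npy$", "", name)]] <- npy_parse(data)
    pos <- dstart + csize
  }
  if (!length(out)) stop("no npy members found in ", path)
  out
}
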