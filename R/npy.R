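# Minimal NPY v1.0 reader/writer for dense numeric arrays.
# Covers little-endian float64/float32, uint8/uint16, C or Fortran order.
# Arrays are written float64, C order, so round-trips are bit-exact.

npy_magic <- as.raw(c(0x93, charToRaw("NUMPY")))

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, npy_magic)) stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  if (as.integer(ver[1]) == 1L) {
    hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  } else {
    hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- prod(shape)
  endian <- if (startsWith(descr, ">")) "big" else "little"
  code <- sub("^[<>=|]", "", descr)
  dat <- switch(code,
    f8 = readBin(con, "double", n, size = 8, endian = endian),
    f4 = readBin(con, "double", n, size = 4, endian = endian),
    u1 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    u2 = as.numeric(readBin(con, "integer", n, size = 2, endian = endian,
                            signed = FALSE)),
    i4 = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    stop("unsupported NPY dtype: ", descr)
  )
  if (length(dat) != n) stop("truncated NPY payload in ", path)
  if (length(shape) <= 1L) return(dat)
  if (fortran) {
    array(dat, dim = shape)
  } else {
    # C order: fastest-varying axis is the last one
    aperm(array(dat, dim = rev(shape)), rev(seq_along(shape)))
  }
}

write_npy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  # emit C order for interoperability
  dat <- if (length(shape) > 1L) aperm(x, rev(seq_along(shape))) else x
  shape_s <- paste0("(", paste(shape, collapse = ", "),
                    if (length(shape) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape_s)
  # pad so that total header size is a multiple of 64
  total <- 6L + 2L + 2L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(dat), con, size = 8, endian = "little")
  invisible(path)
}
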