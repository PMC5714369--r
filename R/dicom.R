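# Minimal DICOM codec: explicit VR, little endian, the RT Plan / RT Dose
# subset this package reads and writes. No preinstalled R or Python DICOM
# library exists in the target environment, so the format handling lives
# here; it is not a general-purpose DICOM implementation.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_ROOT <- "2.25" # UUID-derived numeric root for generated instances

# deterministic instance UID from a key string (no timestamps, so fixture
# generation is reproducible for a fixed seed)
dcm_uid <- function(key) {
  h1 <- strtoi(fnv1a_hex(key), 16L)
  h2 <- strtoi(fnv1a_hex(paste0("arcqa:", key)), 16L)
  sprintf("%s.%.0f.%.0f", UID_ROOT, h1, h2)
}

# ---- byte packing ----------------------------------------------------------

int_to_raw_le <- function(x, size) {
  x <- as.numeric(x)
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_uint_le <- function(r) sum(as.numeric(r) * 256^(seq_along(r) - 1))

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

enc_txt <- function(x, pad = as.raw(0x20)) pad_even(charToRaw(paste(x, collapse = "\\")), pad)
enc_ui  <- function(x) pad_even(charToRaw(x), as.raw(0)) # UIDs pad with NUL
enc_ds  <- function(x) enc_txt(sprintf("%.10g", as.numeric(x)))
enc_is  <- function(x) enc_txt(sprintf("%d", as.integer(x)))
enc_us  <- function(x) do.call(c, lapply(as.integer(x), int_to_raw_le, size = 2))

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

dcm_element <- function(group, element, vr, value_raw) {
  head <- c(int_to_raw_le(group, 2), int_to_raw_le(element, 2), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), int_to_raw_le(length(value_raw), 4), value_raw)
  } else {
    if (length(value_raw) > 65534) stop_config("DICOM element value too long for short VR")
    c(head, int_to_raw_le(length(value_raw), 2), value_raw)
  }
}

# sequence with explicit lengths; items is a list of raw vectors
dcm_sequence <- function(group, element, items) {
  body <- do.call(c, lapply(items, function(it)
    c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE000, 2),
      int_to_raw_le(length(it), 4), it)))
  if (is.null(body)) body <- raw(0)
  dcm_element(group, element, "SQ", body)
}

# assemble a file: 128-byte preamble, DICM, file meta group, dataset
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset_raw) {
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", enc_ui(sop_class_uid)),
    dcm_element(0x0002, 0x0003, "UI", enc_ui(sop_instance_uid)),
    dcm_element(0x0002, 0x0010, "UI", enc_ui(UID_EXPLICIT_VR_LE)),
    dcm_element(0x0002, 0x0012, "UI", enc_ui(paste0(UID_ROOT, ".1982001")))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", int_to_raw_le(length(meta_body), 4)),
            meta_body)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset_raw), con)
  invisible(path)
}

# ---- parsing ---------------------------------------------------------------

# Parses one dataset region [pos, end] of `bytes` into a named list keyed by
# "GGGGEEEE" (upper-case hex). SQ values become lists of item datasets.
# Handles both explicit and undefined (0xFFFFFFFF) sequence/item lengths.
dcm_parse_dataset <- function(bytes, pos, end) {
  out <- list()
  while (pos <= end) {
    group <- raw_to_uint_le(bytes[pos:(pos + 1)])
    element <- raw_to_uint_le(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4
    if (group == 0xFFFE) { # delimiter items should not appear at this level
      len <- raw_to_uint_le(bytes[pos:(pos + 3)]); pos <- pos + 4 + len
      next
    }
    vr <- rawToChar(bytes[pos:(pos + 1)])
    if (vr %in% LONG_VRS) {
      len <- raw_to_uint_le(bytes[(pos + 4):(pos + 7)])
      pos <- pos + 8
    } else {
      len <- raw_to_uint_le(bytes[(pos + 2):(pos + 3)])
      pos <- pos + 4
    }
    key <- sprintf("%04X%04X", group, element)
    if (vr == "SQ") {
      parsed <- dcm_parse_sequence(bytes, pos, len)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop_config("undefined length outside a sequence")
      val_raw <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      out[[key]] <- dcm_decode_value(vr, val_raw)
    }
  }
  out
}

dcm_parse_sequence <- function(bytes, pos, len) {
  undefined <- len == 4294967295
  stop_at <- if (undefined) length(bytes) else pos + len - 1
  items <- list()
  while (pos <= stop_at) {
    group <- raw_to_uint_le(bytes[pos:(pos + 1)])
    element <- raw_to_uint_le(bytes[(pos + 2):(pos + 3)])
    ilen <- raw_to_uint_le(bytes[(pos + 4):(pos + 7)])
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop_config("malformed sequence: expected an item tag")
    if (ilen == 4294967295) {
      # undefined-length item: scan to its delimiter at this nesting level
      iend <- dcm_find_item_end(bytes, pos)
      items[[length(items) + 1L]] <- dcm_parse_dataset(bytes, pos, iend - 1)
      pos <- iend + 8
    } else {
      if (ilen > 0)
        items[[length(items) + 1L]] <- dcm_parse_dataset(bytes, pos, pos + ilen - 1)
      else items[[length(items) + 1L]] <- list()
      pos <- pos + ilen
    }
    if (undefined && pos > length(bytes)) break
  }
  list(items = items, pos = pos)
}

dcm_find_item_end <- function(bytes, pos) {
  depth <- 0
  while (pos + 7 <= length(bytes)) {
    group <- raw_to_uint_le(bytes[pos:(pos + 1)])
    element <- raw_to_uint_le(bytes[(pos + 2):(pos + 3)])
    if (group == 0xFFFE) {
      if (element == 0xE00D && depth == 0) return(pos)
      if (element == 0xE000) depth <- depth # items do not nest directly
      pos <- pos + 8
      next
    }
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- raw_to_uint_le(bytes[(pos + 8):(pos + 11)])
      pos <- pos + 12 + if (len == 4294967295) 0 else len
    } else {
      len <- raw_to_uint_le(bytes[(pos + 6):(pos + 7)])
      pos <- pos + 8 + len
    }
  }
  stop_config("unterminated undefined-length item")
}

dcm_decode_value <- function(vr, val_raw) {
  switch(vr,
    DS = , FD = if (vr == "DS") {
      s <- trimws(rawToChar(val_raw))
      if (nchar(s)) as.numeric(strsplit(s, "\\\\")[[1]]) else numeric(0)
    } else readBin(val_raw, "double", n = length(val_raw) / 8, size = 8,
                   endian = "little"),
    IS = {
      s <- trimws(rawToChar(val_raw))
      if (nchar(s)) as.integer(strsplit(s, "\\\\")[[1]]) else integer(0)
    },
    US = readBin(val_raw, "integer", n = length(val_raw) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = vapply(seq_len(length(val_raw) / 4), function(i)
      raw_to_uint_le(val_raw[(4 * i - 3):(4 * i)]), numeric(1)),
    UI = trimws(rawToChar(val_raw[val_raw != as.raw(0)])),
    CS = , SH = , LO = , ST = , PN = , DA = , TM = trimws(rawToChar(val_raw)),
    val_raw # OB/OW and anything else stay raw
  )
}

dcm_read_file <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  n <- file.info(path)$size
  bytes <- readBin(path, "raw", n = n)
  if (n < 136 || rawToChar(bytes[129:132]) != "DICM")
    stop_config("not a DICOM file (missing DICM marker): %s", path)
  ds <- dcm_parse_dataset(bytes, 133, n)
  ts <- ds[["00020010"]]
  if (!is.null(ts) && ts != UID_EXPLICIT_VR_LE)
    stop_config("unsupported transfer syntax %s", ts)
  ds
}

dcm_get <- function(ds, key, what) {
  v <- ds[[key]]
  if (is.null(v)) stop_config("parse error: missing %s (%s)", what, key)
  v
}
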