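# Minimal DICOM codec (explicit VR little endian) covering the subset of the
# standard needed for RT Plan objects: string/number VRs, nested sequences
# with undefined lengths, and the part-10 file meta header. No pre-installed
# DICOM library exists in this environment, so the package carries its own
# reader/writer for exactly the tags it uses. Not a general DICOM parser.

.dcm_uid_transfer_le <- "1.2.840.10008.1.2.1"
.dcm_uid_rtplan <- "1.2.840.10008.5.1.4.1.1.481.5"
.dcm_uid_impl <- "1.2.826.0.1.3680043.10.9000.1"

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) {
  # writeBin size=4 signed is fine for lengths < 2^31; 0xFFFFFFFF needs care
  if (x == 4294967295) return(as.raw(c(0xff, 0xff, 0xff, 0xff)))
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# Encode one data element. `value` is already a raw vector for non-SQ VRs;
# for SQ it is a list of raw vectors (one encoded dataset per item), written
# with undefined lengths and item/sequence delimiters.
dcm_element <- function(group, element, vr, value) {
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr == "SQ") {
    items <- lapply(value, function(body) {
      c(dcm_u16(0xFFFE), dcm_u16(0xE000), dcm_u32(4294967295), body,
        dcm_u16(0xFFFE), dcm_u16(0xE00D), dcm_u32(0))
    })
    body <- c(do.call(c, c(items, list(raw(0)))),
              dcm_u16(0xFFFE), dcm_u16(0xE0DD), dcm_u32(0))
    return(c(head, as.raw(c(0, 0)), dcm_u32(4294967295), body))
  }
  value <- dcm_pad(value, pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value)), value)
  } else {
    c(head, dcm_u16(length(value)), value)
  }
}

dcm_str_element <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(paste(s, collapse = "\\")))
}

# DS with fixed decimals keeps every value within the 16-byte VR limit while
# preserving round-trip precision well beyond the 1e-4 mm contract.
dcm_ds <- function(group, element, x, digits = 6) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  dcm_str_element(group, element, "DS", s)
}

dcm_is <- function(group, element, x) {
  dcm_str_element(group, element, "IS", sprintf("%d", as.integer(x)))
}

dcm_write_file <- function(path, dataset_body, sop_instance_uid) {
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str_element(0x0002, 0x0002, "UI", .dcm_uid_rtplan),
    dcm_str_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_str_element(0x0002, 0x0010, "UI", .dcm_uid_transfer_le),
    dcm_str_element(0x0002, 0x0012, "UI", .dcm_uid_impl)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta_body), raw(), size = 4,
                                 endian = "little")),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(dataset_body, con)
  path
}

# ---- reader -----------------------------------------------------------------

dcm_read_u16 <- function(buf, i) {
  as.integer(buf[i]) + 256L * as.integer(buf[i + 1])
}
dcm_read_u32 <- function(buf, i) {
  as.numeric(buf[i]) + 256 * as.numeric(buf[i + 1]) +
    65536 * as.numeric(buf[i + 2]) + 16777216 * as.numeric(buf[i + 3])
}

# Parse a run of explicit-VR elements in buf[i..end]; returns a named list
# keyed by lowercase tag "ggggeeee". SQ values are lists of such lists.
dcm_parse <- function(buf, i, end) {
  out <- list()
  while (i <= end - 7) {
    group <- dcm_read_u16(buf, i)
    element <- dcm_read_u16(buf, i + 2)
    if (group == 0xFFFE) {  # delimiter reached inside an undefined-length run
      break
    }
    vr <- rawToChar(buf[(i + 4):(i + 5)])
    if (vr %in% .dcm_long_vrs) {
      len <- dcm_read_u32(buf, i + 8)
      i <- i + 12
    } else {
      len <- dcm_read_u16(buf, i + 6)
      i <- i + 8
    }
    tag <- sprintf("%04x%04x", group, element)
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- dcm_parse_sq_undef(buf, i)
      } else {
        parsed <- dcm_parse_sq_undef(buf, i, hard_end = i + len - 1)
        parsed$next_i <- i + len
      }
      out[[tag]] <- list(vr = "SQ", items = parsed$items)
      i <- parsed$next_i
    } else {
      stopifnot(len != 4294967295)
      value <- if (len > 0) buf[i:(i + len - 1)] else raw(0)
      out[[tag]] <- list(vr = vr, bytes = value)
      i <- i + len
    }
  }
  list(elements = out, next_i = i)
}

dcm_parse_sq_undef <- function(buf, i, hard_end = length(buf)) {
  items <- list()
  repeat {
    if (i > hard_end - 7) break
    group <- dcm_read_u16(buf, i)
    element <- dcm_read_u16(buf, i + 2)
    len <- dcm_read_u32(buf, i + 4)
    i <- i + 8
    if (group == 0xFFFE && element == 0xE0DD) break       # sequence delimiter
    if (group == 0xFFFE && element == 0xE000) {           # item start
      item_end <- if (len == 4294967295) hard_end else i + len - 1
      parsed <- dcm_parse(buf, i, item_end)
      items[[length(items) + 1]] <- parsed$elements
      i <- parsed$next_i
      if (len == 4294967295) {
        # consume the item delimiter the inner parse stopped at
        stopifnot(dcm_read_u16(buf, i) == 0xFFFE,
                  dcm_read_u16(buf, i + 2) == 0xE00D)
        i <- i + 8
      }
      if (i > hard_end) break
    } else {
      stop("malformed sequence structure in DICOM stream")
    }
  }
  list(items = items, next_i = i)
}

dcm_get_str <- function(ds, tag) {
  el <- ds[[tag]]
  if (is.null(el)) return(NULL)
  b <- el$bytes
  while (length(b) && (b[length(b)] == as.raw(0) || b[length(b)] == as.raw(0x20)))
    b <- b[-length(b)]
  rawToChar(b)
}

dcm_get_num <- function(ds, tag) {
  s <- dcm_get_str(ds, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  parsed_meta <- dcm_parse(buf, 133, 140)  # just the (0002,0000) group length
  glen <- readBin(parsed_meta$elements[["00020000"]]$bytes, "integer",
                  size = 4, endian = "little")
  meta <- dcm_parse(buf, parsed_meta$next_i, parsed_meta$next_i + glen - 1)
  ts <- dcm_get_str(meta$elements, "00020010")
  if (!is.null(ts) && ts != .dcm_uid_transfer_le)
    stop("unsupported transfer syntax: ", ts)
  body <- dcm_parse(buf, meta$next_i, length(buf))
  body$elements
}

dcm_new_uid <- function() {
  paste0(.dcm_uid_impl, ".", format(as.integer(Sys.time()) %% 100000000L),
         ".", sample.int(.Machine$integer.max, 1) %% 1000000L)
}
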