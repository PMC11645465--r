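# Minimal DICOM codec for the RTSTRUCT / CT-geometry subset this package
# needs. Reads explicit and implicit VR little-endian files with defined- or
# undefined-length sequences; writes explicit VR little-endian with defined
# lengths. Datasets are ordered named lists keyed "GGGG,EEEE" (upper-case
# hex); each element is list(vr = <chr>, value = <parsed value>). String VRs
# keep the de-padded string verbatim so numeric text (e.g. contour data) can
# be re-emitted byte-identically.

DCM_UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
DCM_UID_RTSTRUCT    <- "1.2.840.10008.5.1.4.1.1.481.3"
DCM_UID_CT          <- "1.2.840.10008.5.1.4.1.1.2"

# Tag dictionary: needed to assign VRs when reading implicit-VR files.
.dcm_dict <- c(
  "0002,0000" = "UL", "0002,0001" = "OB", "0002,0002" = "UI",
  "0002,0003" = "UI", "0002,0010" = "UI", "0002,0012" = "UI",
  "0002,0013" = "SH",
  "0008,0005" = "CS", "0008,0008" = "CS", "0008,0012" = "DA",
  "0008,0013" = "TM", "0008,0016" = "UI", "0008,0018" = "UI",
  "0008,0020" = "DA", "0008,0021" = "DA", "0008,0023" = "DA",
  "0008,0030" = "TM", "0008,0031" = "TM", "0008,0033" = "TM",
  "0008,0050" = "SH", "0008,0060" = "CS", "0008,0070" = "LO",
  "0008,0090" = "PN", "0008,103E" = "LO", "0008,1150" = "UI",
  "0008,1155" = "UI",
  "0010,0010" = "PN", "0010,0020" = "LO", "0010,0030" = "DA",
  "0010,0040" = "CS",
  "0018,0050" = "DS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0010" = "SH",
  "0020,0011" = "IS", "0020,0013" = "IS", "0020,0032" = "DS",
  "0020,0037" = "DS", "0020,0052" = "UI", "0020,1040" = "LO",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "3006,0002" = "SH", "3006,0008" = "DA", "3006,0009" = "TM",
  "3006,0010" = "SQ", "3006,0012" = "SQ", "3006,0014" = "SQ",
  "3006,0016" = "SQ", "3006,0020" = "SQ", "3006,0022" = "IS",
  "3006,0024" = "UI", "3006,0026" = "LO", "3006,0028" = "ST",
  "3006,002A" = "IS", "3006,0036" = "CS", "3006,0039" = "SQ",
  "3006,0040" = "SQ", "3006,0042" = "CS", "3006,0046" = "IS",
  "3006,0048" = "IS", "3006,0050" = "DS", "3006,0080" = "SQ",
  "3006,0082" = "IS", "3006,0084" = "IS", "3006,00A4" = "CS",
  "3006,00A6" = "PN",
  "7FE0,0010" = "OW"
)

.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UI", "UT")

.tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

# ---- encoding -------------------------------------------------------------

.enc_u16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

.enc_u32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

.enc_string <- function(value, vr) {
  s <- paste(as.character(value), collapse = "\\")
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    b <- c(b, pad)
  }
  b
}

.enc_value <- function(vr, value) {
  if (vr %in% .dcm_string_vrs) {
    .enc_string(value, vr)
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  } else if (vr %in% c("OB", "OW", "UN")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else if (vr == "FD") {
    writeBin(as.double(value), raw(), size = 8L, endian = "little")
  } else if (vr == "FL") {
    writeBin(as.double(value), raw(), size = 4L, endian = "little")
  } else {
    stop("unsupported VR for encoding: ", vr)
  }
}

# Encode one element, explicit VR little endian, defined lengths.
.enc_element <- function(key, vr, value) {
  group <- strtoi(substr(key, 1L, 4L), 16L)
  element <- strtoi(substr(key, 6L, 9L), 16L)
  tag <- c(.enc_u16(group), .enc_u16(element))
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- .enc_dataset(item)
      c(.enc_u16(0xFFFE), .enc_u16(0xE000), .enc_u32(length(body)), body)
    })
    body <- do.call(c, c(items, list(raw(0))))
    c(tag, charToRaw("SQ"), as.raw(c(0L, 0L)), .enc_u32(length(body)), body)
  } else if (vr %in% c("OB", "OW", "UN", "UT")) {
    body <- .enc_value(vr, value)
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .enc_u32(length(body)), body)
  } else {
    body <- .enc_value(vr, value)
    if (length(body) > 65534L) {
      stop("element ", key, " too long for short-form VR ", vr)
    }
    c(tag, charToRaw(vr), .enc_u16(length(body)), body)
  }
}

.enc_dataset <- function(dataset) {
  if (length(dataset) == 0L) return(raw(0))
  keys <- names(dataset)
  ord <- order(keys)  # DICOM requires ascending tag order
  parts <- lapply(ord, function(i) {
    el <- dataset[[i]]
    .enc_element(keys[[i]], el$vr, el$value)
  })
  do.call(c, parts)
}

#' @noRd
dcm_write <- function(path, dataset, sop_class_uid, sop_instance_uid) {
  meta <- list(
    "0002,0001" = list(vr = "OB", value = as.raw(c(0L, 1L))),
    "0002,0002" = list(vr = "UI", value = sop_class_uid),
    "0002,0003" = list(vr = "UI", value = sop_instance_uid),
    "0002,0010" = list(vr = "UI", value = DCM_UID_EXPLICIT_LE),
    "0002,0012" = list(vr = "UI", value = "2.25.841239873219873100001"),
    "0002,0013" = list(vr = "SH", value = "RTDEINTERP")
  )
  meta_body <- .enc_dataset(meta)
  meta_bytes <- c(
    .enc_element("0002,0000", "UL", length(meta_body)),
    meta_body
  )
  bytes <- c(raw(128L), charToRaw("DICM"), meta_bytes, .enc_dataset(dataset))
  con <- tryCatch(
    file(path, "wb"),
    error = function(e) stop("cannot open '", path, "' for writing: ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot open '", path, "' for writing: ",
                               conditionMessage(w), call. = FALSE)
  )
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

.dec_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

.dec_u32 <- function(bytes, pos) {
  # returns -1 for 0xFFFFFFFF (undefined length)
  readBin(bytes[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
}

.dec_value <- function(vr, body) {
  if (vr %in% .dcm_string_vrs) {
    # strip trailing NUL/space padding before text conversion
    while (length(body) &&
           (body[length(body)] == as.raw(0L) ||
            body[length(body)] == as.raw(0x20))) {
      body <- body[-length(body)]
    }
    rawToChar(body)
  } else if (vr == "US") {
    readBin(body, "integer", n = length(body) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(body, "integer", n = length(body) %/% 4L, size = 4L,
            endian = "little")
  } else if (vr == "FD") {
    readBin(body, "double", n = length(body) %/% 8L, size = 8L,
            endian = "little")
  } else if (vr == "FL") {
    readBin(body, "double", n = length(body) %/% 4L, size = 4L,
            endian = "little")
  } else {
    body  # OB/OW/UN and anything unrecognised stay raw
  }
}

# Reads elements from bytes starting at cur$pos until end_pos (exclusive) or
# an item delimiter. cur is an environment holding pos; explicit selects VR
# encoding.
.dec_dataset <- function(bytes, cur, explicit, end_pos) {
  out <- list()
  while (cur$pos < end_pos) {
    group <- .dec_u16(bytes, cur$pos)
    element <- .dec_u16(bytes, cur$pos + 2L)
    if (group == 0xFFFE && element == 0xE00D) {  # item delimiter
      cur$pos <- cur$pos + 8L
      break
    }
    cur$pos <- cur$pos + 4L
    key <- .tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(bytes[cur$pos:(cur$pos + 1L)])
      cur$pos <- cur$pos + 2L
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        cur$pos <- cur$pos + 2L  # reserved
        len <- .dec_u32(bytes, cur$pos)
        cur$pos <- cur$pos + 4L
      } else {
        len <- .dec_u16(bytes, cur$pos)
        cur$pos <- cur$pos + 2L
      }
    } else {
      vr <- .dcm_dict[[key]]
      if (is.null(vr) || is.na(vr)) vr <- "UN"
      len <- .dec_u32(bytes, cur$pos)
      cur$pos <- cur$pos + 4L
    }
    if (vr == "SQ" || (vr == "UN" && len == -1L)) {
      value <- .dec_sequence(bytes, cur, explicit, len)
      out[[key]] <- list(vr = "SQ", value = value)
    } else {
      if (len == -1L) stop("undefined length on non-sequence element ", key)
      body <- if (len > 0L) bytes[cur$pos:(cur$pos + len - 1L)] else raw(0)
      cur$pos <- cur$pos + len
      out[[key]] <- list(vr = vr, value = .dec_value(vr, body))
    }
  }
  out
}

.dec_sequence <- function(bytes, cur, explicit, len) {
  end_pos <- if (len == -1L) length(bytes) + 1L else cur$pos + len
  items <- list()
  while (cur$pos < end_pos) {
    group <- .dec_u16(bytes, cur$pos)
    element <- .dec_u16(bytes, cur$pos + 2L)
    if (group == 0xFFFE && element == 0xE0DD) {  # sequence delimiter
      cur$pos <- cur$pos + 8L
      break
    }
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected item tag, found ",
           .tag_key(group, element))
    }
    item_len <- .dec_u32(bytes, cur$pos + 4L)
    cur$pos <- cur$pos + 8L
    item_end <- if (item_len == -1L) end_pos else cur$pos + item_len
    items[[length(items) + 1L]] <- .dec_dataset(bytes, cur, explicit, item_end)
  }
  items
}

#' @noRd
dcm_read <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  size <- file.info(path)$size
  bytes <- readBin(path, "raw", n = size)
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop("'", path, "' is not a DICOM part-10 file (missing DICM magic)",
         call. = FALSE)
  }
  cur <- new.env(parent = emptyenv())
  cur$pos <- 133L
  # file meta group is always explicit VR little endian
  if (.dec_u16(bytes, cur$pos) != 2L) stop("missing file meta group")
  meta_first <- .dec_dataset(bytes, cur, explicit = TRUE,
                             end_pos = cur$pos + 12L)
  glen <- meta_first[["0002,0000"]]$value
  meta_rest <- .dec_dataset(bytes, cur, explicit = TRUE,
                            end_pos = cur$pos + glen)
  meta <- c(meta_first, meta_rest)
  ts <- meta[["0002,0010"]]$value
  explicit <- !identical(ts, DCM_UID_IMPLICIT_LE)
  if (!ts %in% c(DCM_UID_EXPLICIT_LE, DCM_UID_IMPLICIT_LE)) {
    stop("unsupported transfer syntax '", ts,
         "' (only little-endian uncompressed syntaxes are supported)",
         call. = FALSE)
  }
  data <- .dec_dataset(bytes, cur, explicit, end_pos = length(bytes) + 1L)
  list(meta = meta, dataset = data, transfer_syntax = ts, path = path)
}

# Convenience accessors on decoded datasets
.dcm_get <- function(dataset, key, default = NULL) {
  el <- dataset[[key]]
  if (is.null(el)) default else el$value
}

.dcm_num <- function(dataset, key, default = NULL) {
  v <- .dcm_get(dataset, key)
  if (is.null(v)) return(default)
  as.numeric(strsplit(v, "\\", fixed = TRUE)[[1L]])
}

.dcm_int <- function(dataset, key, default = NULL) {
  v <- .dcm_num(dataset, key, default)
  if (is.null(v)) NULL else as.integer(v)
}
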