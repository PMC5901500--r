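#' Construct a chromatogram object
#'
#' A chromatogram holds the four-channel fluorescence trace of a Sanger read
#' together with its basecalls. Channels are ordered A, C, G, T. All indices
#' in this package are 1-based.
#'
#' @param trace Numeric matrix with four columns (A, C, G, T), one row per
#'   trace point; intensities must be non-negative.
#' @param basecall_positions Strictly increasing integer vector of trace row
#'   indices, one per called base.
#' @param called_sequence Single string of called bases (IUPAC codes allowed),
#'   same length as `basecall_positions`.
#' @param sample_id Sample identifier.
#' @param direction Sequencing direction, `"F"` or `"R"`.
#'
#' @return An object of class `chromatogram`: a list with elements `trace`,
#'   `basecall_positions`, `called_sequence`, `sample_id`, `direction`.
#' @export
chromatogram <- function(trace, basecall_positions, called_sequence,
                         sample_id = "sample", direction = c("F", "R")) {
  direction <- match.arg(direction)
  trace <- as.matrix(trace)
  if (ncol(trace) != 4L) {
    stop("trace must have four channels (A, C, G, T)", call. = FALSE)
  }
  colnames(trace) <- c("A", "C", "G", "T")
  storage.mode(trace) <- "double"
  if (nrow(trace) == 0L) stop("trace has zero length", call. = FALSE)
  if (any(trace < 0)) stop("trace intensities must be non-negative", call. = FALSE)
  basecall_positions <- as.integer(basecall_positions)
  if (length(basecall_positions) == 0L) {
    stop("chromatogram has no basecalls", call. = FALSE)
  }
  if (any(diff(basecall_positions) <= 0L)) {
    stop("basecall_positions must be strictly increasing", call. = FALSE)
  }
  if (min(basecall_positions) < 1L || max(basecall_positions) > nrow(trace)) {
    stop("basecall_positions outside trace", call. = FALSE)
  }
  called_sequence <- toupper(as.character(called_sequence))
  if (nchar(called_sequence) != length(basecall_positions)) {
    stop("called_sequence length must equal number of basecall positions",
         call. = FALSE)
  }
  structure(
    list(trace = trace,
         basecall_positions = basecall_positions,
         called_sequence = called_sequence,
         sample_id = as.character(sample_id),
         direction = direction),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s (%s): %d trace points, %d basecalls\n",
              x$sample_id, x$direction, nrow(x$trace),
              length(x$basecall_positions)))
  invisible(x)
}

# ---- ABIF (AB1) reading ----------------------------------------------------

abif_read_entry <- function(con, data_start, entry) {
  # data <= 4 bytes is stored inline in the offset field (ABIF convention)
  if (entry$data_size <= 4L) {
    raw <- entry$offset_raw[seq_len(entry$data_size)]
  } else {
    seek(con, entry$data_offset)
    raw <- readBin(con, "raw", n = entry$data_size)
    if (length(raw) < entry$data_size) {
      stop(sprintf("AB1 file truncated while reading record %s%d",
                   entry$name, entry$number), call. = FALSE)
    }
  }
  switch(as.character(entry$type),
    "2"  = rawToChar(raw),                                    # char
    "18" = if (length(raw) > 1) rawToChar(raw[-1]) else "",   # pString
    "19" = rawToChar(raw[raw != as.raw(0)]),                  # cString
    "4"  = readBin(raw, "integer", n = entry$n_elements, size = 2,
                   signed = TRUE, endian = "big"),
    "5"  = readBin(raw, "integer", n = entry$n_elements, size = 4,
                   endian = "big"),
    "1"  = as.integer(raw),
    "7"  = readBin(raw, "double", n = entry$n_elements, size = 4,
                   endian = "big"),
    "8"  = readBin(raw, "double", n = entry$n_elements, size = 8,
                   endian = "big"),
    raw
  )
}

#' Read an AB1 (ABIF) Sanger chromatogram
#'
#' Parses the ABIF container directly: processed trace channels (`DATA` 9-12),
#' dye order (`FWO_1`), basecall positions (`PLOC`) and called bases (`PBAS`).
#' The channel-to-base mapping is resolved from the file's dye-order record,
#' so traces are always returned in A, C, G, T order regardless of instrument
#' dye layout.
#'
#' @param path Path to an AB1 file.
#' @param direction Sequencing direction to record, `"F"` or `"R"` (ABIF files
#'   do not store this; it comes from the assay design).
#' @param sample_id Optional sample identifier; defaults to the file name.
#'
#' @return A [chromatogram()].
#' @export
read_ab1 <- function(path, direction = c("F", "R"), sample_id = NULL) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || rawToChar(magic) != "ABIF") {
    stop("not an ABIF container (missing ABIF magic): ", path, call. = FALSE)
  }
  readBin(con, "integer", n = 1, size = 2, endian = "big")  # version
  # root directory entry (28 bytes): name, number, type, elsize, nelem,
  # dsize, doffset, dhandle
  readBin(con, "raw", n = 4)                                 # "tdir"
  readBin(con, "integer", n = 1, size = 4, endian = "big")   # number
  readBin(con, "integer", n = 2, size = 2, endian = "big")   # type, elsize
  n_entries <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  readBin(con, "integer", n = 1, size = 4, endian = "big")   # dsize
  dir_offset <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(n_entries) == 0 || length(dir_offset) == 0 || n_entries < 1) {
    stop("ABIF directory missing or empty: ", path, call. = FALSE)
  }
  seek(con, dir_offset)
  dir_raw <- readBin(con, "raw", n = 28L * n_entries)
  if (length(dir_raw) < 28L * n_entries) {
    stop("ABIF directory truncated: ", path, call. = FALSE)
  }
  entries <- lapply(seq_len(n_entries) - 1L, function(i) {
    e <- dir_raw[i * 28L + seq_len(28L)]
    list(
      name = rawToChar(e[1:4]),
      number = readBin(e[5:8], "integer", size = 4, endian = "big"),
      type = readBin(e[9:10], "integer", size = 2, endian = "big"),
      n_elements = readBin(e[13:16], "integer", size = 4, endian = "big"),
      data_size = readBin(e[17:20], "integer", size = 4, endian = "big"),
      data_offset = readBin(e[21:24], "integer", size = 4, endian = "big"),
      offset_raw = e[21:24]
    )
  })
  find <- function(name, number) {
    hit <- Filter(function(e) e$name == name && e$number == number, entries)
    if (length(hit) == 0) return(NULL)
    abif_read_entry(con, NULL, hit[[1]])
  }
  need <- function(x, what) {
    if (is.null(x)) {
      stop("ABIF record missing: ", what, " in ", path, call. = FALSE)
    }
    x
  }
  dye_order <- toupper(need(find("FWO_", 1L), "FWO_ (dye order)"))
  channels <- lapply(9:12, function(k) {
    need(find("DATA", k), sprintf("DATA%d (trace channel)", k))
  })
  lens <- vapply(channels, length, 1L)
  if (any(lens == 0L) || length(unique(lens)) != 1L) {
    stop("ABIF trace channels empty or of unequal length: ", path,
         call. = FALSE)
  }
  bases <- strsplit(dye_order, "")[[1]]
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("ABIF dye order record does not name the four bases: ", dye_order,
         call. = FALSE)
  }
  trace <- matrix(0, nrow = lens[1], ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in 1:4) trace[, bases[k]] <- channels[[k]]
  ploc <- find("PLOC", 2L)
  if (is.null(ploc)) ploc <- find("PLOC", 1L)
  ploc <- need(ploc, "PLOC (basecall positions)")
  pbas <- find("PBAS", 2L)
  if (is.null(pbas)) pbas <- find("PBAS", 1L)
  pbas <- need(pbas, "PBAS (called bases)")
  if (is.null(sample_id)) {
    smpl <- find("SMPL", 1L)
    sample_id <- if (!is.null(smpl)) smpl else basename(path)
  }
  # ABIF PLOC is 0-based; convert to 1-based rows
  chromatogram(trace, as.integer(ploc) + 1L, pbas,
               sample_id = sample_id, direction = direction)
}

# ---- plain-text trace dialect ----------------------------------------------

#' Read a plain-text chromatogram trace file
#'
#' The dialect written by [simulate_trace()] and [write_trace_table()]:
#' header lines `#sample=`, `#direction=`, `#basecalls=` (comma-separated
#' 1-based trace row indices) and `#sequence=`, followed by four tab-separated
#' intensity columns in A, C, G, T order.
#'
#' @param path Path to a trace file.
#' @return A [chromatogram()].
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trace file: ", path, call. = FALSE)
  is_header <- startsWith(lines, "#")
  headers <- lines[is_header]
  get_header <- function(key) {
    hit <- headers[startsWith(headers, paste0("#", key, "="))]
    if (length(hit) == 0L) {
      stop("trace file missing header '#", key, "=': ", path, call. = FALSE)
    }
    sub(paste0("^#", key, "="), "", hit[1])
  }
  sample_id <- get_header("sample")
  direction <- get_header("direction")
  basecalls <- as.integer(strsplit(get_header("basecalls"), ",")[[1]])
  sequence <- get_header("sequence")
  body <- lines[!is_header & nzchar(lines)]
  if (length(body) == 0L) stop("trace file has no intensity rows: ", path,
                               call. = FALSE)
  mat <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  if (ncol(mat) != 4L || anyNA(mat)) {
    stop("trace file must have four numeric tab-separated channel columns: ",
         path, call. = FALSE)
  }
  chromatogram(mat, basecalls, sequence, sample_id = sample_id,
               direction = direction)
}

#' Write a chromatogram in the plain-text trace dialect
#'
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  header <- c(
    paste0("#sample=", chrom$sample_id),
    paste0("#direction=", chrom$direction),
    paste0("#basecalls=", paste(chrom$basecall_positions, collapse = ",")),
    paste0("#sequence=", chrom$called_sequence)
  )
  body <- apply(chrom$trace, 1L, function(r) {
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- variant location and peak extraction ----------------------------------

iupac_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
}

#' Reverse complement a base string (IUPAC-aware)
#'
#' @param x Base string.
#' @return The reverse complement.
#' @export
reverse_complement <- function(x) {
  paste(rev(strsplit(iupac_complement(x), "")[[1]]), collapse = "")
}

#' Locate a variant basecall by its flanking sequences
#'
#' Finds the unique basecall index whose upstream context equals `flank5` and
#' downstream context equals `flank3` exactly; the call at the variant itself
#' may be any base (heterozygous positions are typically called as IUPAC
#' ambiguity codes). Matching is exact: extend the flanks rather than allow
#' mismatches.
#'
#' @param chrom A [chromatogram()].
#' @param flank5,flank3 Non-empty base strings flanking the variant on the
#'   sequenced strand (for reverse reads, pass reverse-complemented flanks).
#' @return The 1-based basecall index of the variant.
#' @export
locate_variant_index <- function(chrom, flank5, flank3) {
  stopifnot(inherits(chrom, "chromatogram"))
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (!nzchar(flank5) || !nzchar(flank3)) {
    stop("flanks must be non-empty", call. = FALSE)
  }
  seq <- chrom$called_sequence
  n <- nchar(seq)
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (i - n5 < 1L || i + n3 > n) next
    if (substr(seq, i - n5, i - 1L) == flank5 &&
        substr(seq, i + 1L, i + n3) == flank3) {
      hits <- c(hits, i)
    }
  }
  if (length(hits) == 0L) {
    stop("flanks not found in called sequence (extend or check flanks)",
         call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop(sprintf("flanks match %d positions (%s): extend flanks",
                 length(hits), paste(hits, collapse = ", ")), call. = FALSE)
  }
  hits
}

#' Construct a peak pair
#'
#' The two allele peak heights for one SNP in one sample, template and
#' sequencing direction — the raw input of the allelic-ratio computation.
#'
#' @param snp_id SNP identifier.
#' @param allele1,allele2 Distinct single bases as read on the sequenced
#'   strand; `height1`/`height2` are their peak intensities.
#' @param height1,height2 Non-negative peak intensities (fluorescence units).
#' @param template `"cDNA"` or `"gDNA"`.
#' @param direction `"F"` or `"R"`.
#' @param sample_id Sample identifier.
#' @param qc_flags Character vector of QC failure codes (empty when clean).
#' @return A `peak_pair` object (named list).
#' @export
peak_pair <- function(snp_id, allele1, allele2, height1, height2,
                      template = c("cDNA", "gDNA"), direction = c("F", "R"),
                      sample_id = "sample", qc_flags = character(0)) {
  template <- match.arg(template)
  direction <- match.arg(direction)
  allele1 <- toupper(allele1); allele2 <- toupper(allele2)
  if (allele1 == allele2) stop("alleles must differ", call. = FALSE)
  if (height1 < 0 || height2 < 0) {
    stop("peak heights must be non-negative", call. = FALSE)
  }
  structure(
    list(snp_id = snp_id, allele1 = allele1, allele2 = allele2,
         height1 = as.numeric(height1), height2 = as.numeric(height2),
         template = template, direction = direction,
         sample_id = as.character(sample_id),
         qc_flags = as.character(qc_flags)),
    class = "peak_pair"
  )
}

local_peak_spacing <- function(chrom, index) {
  pos <- chrom$basecall_positions
  n <- length(pos)
  if (n == 1L) return(nrow(chrom$trace) / 2)
  gaps <- c(if (index > 1L) pos[index] - pos[index - 1L],
            if (index < n) pos[index + 1L] - pos[index])
  mean(gaps)
}

#' Extract the two allele peak heights at a variant position
#'
#' Each height is the maximum intensity of the allele's channel within a
#' window of `window_fraction` times the local inter-peak spacing around the
#' basecall position. The local spacing is the mean distance to the two
#' neighbouring basecalls (single neighbour at trace ends). The half-spacing
#' default keeps neighbouring peaks out of the window.
#'
#' @param chrom A [chromatogram()].
#' @param index 1-based basecall index of the variant (see
#'   [locate_variant_index()]).
#' @param allele1,allele2 Distinct bases on the sequenced strand.
#' @param window_fraction Half-width of the search window as a fraction of the
#'   local inter-peak spacing; default 0.5.
#' @param snp_id,template Passed through to the returned [peak_pair()].
#' @return A [peak_pair()].
#' @export
extract_peak_pair <- function(chrom, index, allele1, allele2,
                              window_fraction = 0.5,
                              snp_id = "snp", template = "cDNA") {
  stopifnot(inherits(chrom, "chromatogram"))
  index <- as.integer(index)
  if (index < 1L || index > length(chrom$basecall_positions)) {
    stop("variant index outside basecalls", call. = FALSE)
  }
  allele1 <- toupper(allele1); allele2 <- toupper(allele2)
  if (!all(c(allele1, allele2) %in% c("A", "C", "G", "T"))) {
    stop("alleles must be unambiguous bases", call. = FALSE)
  }
  center <- chrom$basecall_positions[index]
  half <- window_fraction * local_peak_spacing(chrom, index)
  lo <- max(1L, as.integer(ceiling(center - half)))
  hi <- min(nrow(chrom$trace), as.integer(floor(center + half)))
  if (lo > hi) stop("empty extraction window", call. = FALSE)
  window <- lo:hi
  peak_pair(
    snp_id = snp_id, allele1 = allele1, allele2 = allele2,
    height1 = max(chrom$trace[window, allele1]),
    height2 = max(chrom$trace[window, allele2]),
    template = template, direction = chrom$direction,
    sample_id = chrom$sample_id
  )
}

#' Quality-control assessment of an extracted peak pair
#'
#' Adds QC failure flags; it never raises. Flags:
#' \describe{
#'   \item{`low_signal`}{either allele height below `min_signal` times the
#'     median flanking baseline of its own channel (baseline = channel
#'     intensity at the flanking basecall positions where that channel is not
#'     the called base);}
#'   \item{`offtarget_peak`}{a third base's peak at the variant exceeds
#'     `max_offtarget` times the smaller allele height;}
#'   \item{`poor_context`}{mean flanking peak prominence (called-channel
#'     height relative to the sum of all four channels at the call) below
#'     `min_context_purity` — a proxy for basecall quality.}
#' }
#' Flagged pairs are excluded from DAE by default downstream.
#'
#' @param pair A [peak_pair()] extracted from `chrom` at `index`.
#' @param chrom The source [chromatogram()].
#' @param index 1-based basecall index the pair was extracted at.
#' @param config List of thresholds: `min_signal` (default 5),
#'   `max_offtarget` (default 0.5), `min_context_purity` (default 0.6),
#'   `n_flank` (default 5 basecalls each side).
#' @return `pair` with `qc_flags` filled in.
#' @export
qc_assess <- function(pair, chrom, index, config = list()) {
  stopifnot(inherits(pair, "peak_pair"), inherits(chrom, "chromatogram"))
  cfg <- utils::modifyList(
    list(min_signal = 5, max_offtarget = 0.5, min_context_purity = 0.6,
         n_flank = 5L),
    config
  )
  flags <- character(0)
  pos <- chrom$basecall_positions
  n <- length(pos)
  flank_idx <- setdiff(
    max(1L, index - cfg$n_flank):min(n, index + cfg$n_flank), index
  )
  flank_pos <- pos[flank_idx]
  flank_base <- strsplit(chrom$called_sequence, "")[[1]][flank_idx]

  baseline_of <- function(channel) {
    off <- flank_pos[flank_base != channel]
    if (length(off) == 0L) return(0)
    stats::median(chrom$trace[off, channel])
  }
  if (pair$height1 < cfg$min_signal * baseline_of(pair$allele1) ||
      pair$height2 < cfg$min_signal * baseline_of(pair$allele2)) {
    flags <- c(flags, "low_signal")
  }

  # off-target scan: quarter-spacing around the call, so that the tails of
  # neighbouring peaks do not masquerade as contamination at the variant
  center <- pos[index]
  half <- 0.25 * local_peak_spacing(chrom, index)
  window <- max(1L, as.integer(ceiling(center - half))):
    min(nrow(chrom$trace), as.integer(floor(center + half)))
  others <- setdiff(c("A", "C", "G", "T"), c(pair$allele1, pair$allele2))
  third <- max(apply(chrom$trace[window, others, drop = FALSE], 2L, max))
  minor <- min(pair$height1, pair$height2)
  if (minor > 0 && third > cfg$max_offtarget * minor) {
    flags <- c(flags, "offtarget_peak")
  }

  if (length(flank_idx) > 0L) {
    purity <- vapply(seq_along(flank_idx), function(j) {
      p <- flank_pos[j]
      b <- flank_base[j]
      if (!b %in% c("A", "C", "G", "T")) return(NA_real_)
      tot <- sum(chrom$trace[p, ])
      if (tot <= 0) return(0)
      chrom$trace[p, b] / tot
    }, 1)
    purity <- purity[!is.na(purity)]
    if (length(purity) > 0L && mean(purity) < cfg$min_context_purity) {
      flags <- c(flags, "poor_context")
    }
  }
  pair$qc_flags <- flags
  pair
}

# ---- peak-height tables ----------------------------------------------------

#' Read or write a peak-height table
#'
#' The exchange TSV dialect between trace quantification and the DAE core:
#' columns `sample_id`, `group`, `template`, `direction`, `snp_id`, `allele1`,
#' `allele2`, `height1`, `height2`, `qc_flags` (comma-separated codes, empty
#' when clean).
#'
#' @param path File path.
#' @return `read_peak_table()`: a tibble with the columns above.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "group", "template", "direction", "snp_id",
                "allele1", "allele2", "height1", "height2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("peak table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$height1 <- as.numeric(df$height1)
  df$height2 <- as.numeric(df$height2)
  if (is.null(df$qc_flags)) df$qc_flags <- ""
  df$qc_flags[is.na(df$qc_flags)] <- ""
  tibble::as_tibble(df)
}

#' @rdname read_peak_table
#' @param peaks Tibble/data frame of peak rows (as from
#'   [simulate_peak_table()]).
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
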