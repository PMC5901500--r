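# Writes a minimal but valid ABIF (AB1) container byte-by-byte, independent
# of the package's reader. Channels are supplied in A, C, G, T order and
# written in the file's dye order; ploc is 0-based as on disk.
write_synthetic_ab1 <- function(path, channels, ploc0, sequence,
                                dye_order = "GATC") {
  stopifnot(setequal(names(channels), c("A", "C", "G", "T")))
  dye <- strsplit(dye_order, "")[[1]]
  recs <- list()
  for (k in 1:4) {
    recs[[length(recs) + 1L]] <- list(name = "DATA", number = 8L + k,
                                      type = 4L, elsize = 2L,
                                      data = as.integer(round(channels[[dye[k]]])))
  }
  recs[[length(recs) + 1L]] <- list(name = "FWO_", number = 1L, type = 2L,
                                    elsize = 1L, data = dye_order)
  recs[[length(recs) + 1L]] <- list(name = "PLOC", number = 2L, type = 4L,
                                    elsize = 2L, data = as.integer(ploc0))
  recs[[length(recs) + 1L]] <- list(name = "PBAS", number = 2L, type = 2L,
                                    elsize = 1L, data = sequence)

  payload <- lapply(recs, function(r) {
    if (r$type == 2L) charToRaw(r$data)
    else writeBin(r$data, raw(), size = r$elsize, endian = "big")
  })
  sizes <- vapply(payload, length, 1L)
  nelem <- vapply(recs, function(r) {
    if (r$type == 2L) nchar(r$data) else length(r$data)
  }, 1L)

  header_len <- 128L
  offsets <- header_len + c(0L, cumsum(sizes))[seq_along(sizes)]
  dir_offset <- header_len + sum(sizes)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  writeBin(101L, con, size = 2, endian = "big")
  # root directory entry
  writeBin(charToRaw("tdir"), con)
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(c(1023L, 28L), con, size = 2, endian = "big")
  writeBin(c(length(recs), length(recs) * 28L, dir_offset, 0L), con,
           size = 4, endian = "big")
  writeBin(raw(header_len - 34L), con)
  for (p in payload) writeBin(p, con)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    writeBin(charToRaw(r$name), con)
    writeBin(r$number, con, size = 4, endian = "big")
    writeBin(c(r$type, r$elsize), con, size = 2, endian = "big")
    writeBin(c(nelem[i], sizes[i]), con, size = 4, endian = "big")
    if (sizes[i] <= 4L) {
      inline <- c(payload[[i]], raw(4L - sizes[i]))
      writeBin(inline, con)
    } else {
      writeBin(offsets[i], con, size = 4, endian = "big")
    }
    writeBin(0L, con, size = 4, endian = "big")
  }
  invisible(path)
}

# small deterministic chromatogram with one Gaussian peak per base
make_test_chromatogram <- function(sequence = "ACGTYGCA", variant_index = 5L,
                                   allele_heights = c(C = 200, T = 100),
                                   spacing = 10, peak_sd = 2,
                                   direction = "F", sample_id = "t1") {
  simulate_trace(sequence, variant_index, allele_heights,
                 peak_spacing = spacing, peak_sd = peak_sd,
                 base_amplitude = 300, noise_floor = 0,
                 sample_id = sample_id, direction = direction)
}
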