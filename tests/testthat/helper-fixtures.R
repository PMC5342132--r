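# Shared fixture builders. All data are generated in code at test time.

tiny_events <- function(values, channels = NULL, id = "tiny") {
  values <- as.matrix(values)
  if (is.null(channels)) channels <- paste0("CH", seq_len(ncol(values)))
  event_matrix(values, channels, id)
}

# Two well-separated clouds in p dimensions as a scaled training set.
separable_training_set <- function(n_pos = 50, n_neg = 150, p = 2, gap = 4,
                                   seed = 42, spread = 0.3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_pos * p, mean = gap / 2, sd = spread), ncol = p),
             matrix(rnorm(n_neg * p, mean = -gap / 2, sd = spread), ncol = p))
  colnames(X) <- paste0("F", seq_len(p))
  structure(list(features = X,
                 flags = c(rep(1L, n_pos), rep(0L, n_neg)),
                 sources = c(rep("diag", n_pos), rep("donor1", n_neg))),
            class = "training_set")
}

# A quick small-scale synthetic patient for pipeline unit tests.
quick_patient <- function(seed = 11, fractions = c(0.001, 0.05)) {
  make_synthetic_patient(seed = seed, followup_fractions = fractions,
                         n_blasts = 3000, n_donor_events = 600,
                         n_followup = 20000, n_donors = 5L)
}

# Craft an FCS 3.0 file with $DATATYPE I directly (independent of write_fcs),
# to exercise the reader's integer/log-amplification decode path.
write_fcs_integer_fixture <- function(path, mat, ranges, decades,
                                      offsets = rep(0, ncol(mat)), bits = 16L) {
  n_tot <- nrow(mat); n_par <- ncol(mat)
  kw <- c("$MODE", "L", "$DATATYPE", "I", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0")
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), paste0("P", i),
            sprintf("$P%dB", i), as.character(bits),
            sprintf("$P%dE", i), sprintf("%g,%g", decades[i], offsets[i]),
            sprintf("$P%dR", i), as.character(ranges[i]))
  }
  data_len <- n_tot * n_par * (bits %/% 8L)
  build_text <- function(kv) paste0("/", paste(kv, collapse = "/"), "/")
  text0 <- build_text(c(kw, "$BEGINDATA", strrep("0", 10), "$ENDDATA", strrep("0", 10)))
  text_beg <- 58L
  text_end <- text_beg + nchar(text0) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + data_len - 1L
  text <- build_text(c(kw, "$BEGINDATA", formatC(data_beg, width = 10, flag = "0"),
                       "$ENDDATA", formatC(data_end, width = 10, flag = "0")))
  header <- paste0("FCS3.0    ",
                   formatC(text_beg, width = 8), formatC(text_end, width = 8),
                   formatC(data_beg, width = 8), formatC(data_end, width = 8),
                   formatC(0, width = 8), formatC(0, width = 8))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.integer(t(mat)), con, size = bits %/% 8L, endian = "little")
  invisible(path)
}

# Patch bytes of an existing file (for corrupt-file error tests).
patch_file_bytes <- function(path, at, replacement) {
  raw <- readBin(path, "raw", file.info(path)$size)
  raw[at:(at + length(replacement) - 1L)] <- replacement
  writeBin(raw, path)
  invisible(path)
}
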