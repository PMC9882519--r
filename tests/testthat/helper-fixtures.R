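# shared fixture builders; everything is generated in code

tdict <- toy_genome()

seg_row <- function(chrom, start, end, total, major, minor,
                    l2 = log2(total / 2 + 1e-9)) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = total,
             major_cn = major, minor_cn = minor, log2_ratio = l2)
}

diploid_segments <- function(dict = tdict) {
  do.call(rbind, lapply(seq_len(nrow(dict$chroms)), function(i) {
    seg_row(dict$chroms$chrom[i], 0, dict$chroms$length[i], 2, 1, 1, 0)
  }))
}

make_sv <- function(id, chrom1, pos1, strand1, chrom2, pos2, strand2,
                    svclass = NULL) {
  if (is.null(svclass)) {
    svclass <- if (chrom1 != chrom2) "BND"
      else if (strand1 == "+" && strand2 == "-") "DEL"
      else if (strand1 == "-" && strand2 == "+") "DUP"
      else "INV"
  }
  data.frame(sv_id = id, chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             svclass = svclass, inserted_seq = NA_character_)
}

make_profile <- function(id = "S1", segments = diploid_segments(),
                         svs = NULL, baf = NULL, small = NULL,
                         purity = 0.8, cohort = "TP53_AML") {
  sample_profile(id, cohort, segments = segments, baf_sites = baf,
                 svs = svs, small_variants = small, purity = purity,
                 dict = tdict)
}

random_svs <- function(n, chrom = "chrT1", span = c(1e6, 40e6)) {
  pos1 <- sort(round(runif(n, span[1], span[2] - 2e6)))
  len <- round(runif(n, 1e4, 2e6))
  ori <- sample(1:3, n, replace = TRUE)
  s1 <- c("+", "-", "+")[ori]
  s2 <- c("-", "+", "+")[ori]
  cls <- c("DEL", "DUP", "INV")[ori]
  data.frame(sv_id = sprintf("r%03d", seq_len(n)), chrom1 = chrom,
             pos1 = pos1, strand1 = s1, chrom2 = chrom, pos2 = pos1 + len,
             strand2 = s2, svclass = cls, inserted_seq = NA_character_)
}

# full toy-genome segment table with event pieces spliced into one chromosome
splice_pieces_for_test <- function(pieces, chrom, dict = tdict) {
  len <- chrom_length(dict, chrom)
  s <- min(pieces$start); e <- max(pieces$end)
  host <- rbind(
    if (s > 0) data.frame(start = 0, end = s, total = 2, major = 1,
                          minor = 1),
    pieces,
    if (e < len) data.frame(start = e, end = len, total = 2, major = 1,
                            minor = 1))
  seg <- data.frame(chrom = chrom, start = host$start, end = host$end,
                    total_cn = host$total, major_cn = host$major,
                    minor_cn = host$minor,
                    log2_ratio = log2(pmax(host$total, 0.1) / 2))
  others <- diploid_segments(dict)
  rbind(seg, others[others$chrom != chrom, ])
}

# small cohort simulated once and reused across test files would leak
# between files; each file builds what it needs instead.
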