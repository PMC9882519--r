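#' @title Data model and typed I/O
#'
#' @description
#' Every downstream analysis consumes the typed tables defined here. All
#' internal coordinates are 0-based half-open; 1-based formats (VCF, SAM)
#' are converted at the boundary so only one convention exists inside the
#' package.
#'
#' Table layouts:
#' \describe{
#'   \item{segments}{`chrom, start, end, total_cn, major_cn, minor_cn,
#'     log2_ratio` -- allele-specific copy-number segments, non-overlapping
#'     and sorted per chromosome, with `major_cn >= minor_cn >= 0` and
#'     `total_cn = major_cn + minor_cn` (within 0.01).}
#'   \item{baf_sites}{`chrom, pos, baf, depth` -- heterozygous-site
#'     B-allele fractions.}
#'   \item{svs}{`sv_id, chrom1, pos1, strand1, chrom2, pos2, strand2,
#'     svclass, inserted_seq` -- breakend pairs; `svclass` is `BND` iff
#'     the two breakends are on different chromosomes, and
#'     intrachromosomal records have `pos1 <= pos2`.}
#'   \item{small_variants}{`chrom, pos, ref, alt, vaf, gene, effect`.}
#' }
#' @name core_io
NULL

sv_classes <- c("DEL", "DUP", "INS", "INV", "BND")

#' Validate a copy-number segment table
#'
#' @param seg segments data.frame (see [core_io]).
#' @param dict reference dictionary.
#' @return the validated data.frame (sorted), invisibly usable downstream.
#' @export
validate_segments <- function(seg, dict) {
  need <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn",
            "log2_ratio")
  check_that(all(need %in% names(seg)), "segment table missing columns: %s",
             paste(setdiff(need, names(seg)), collapse = ","))
  if (nrow(seg) == 0) return(seg)
  check_that(all(seg$start >= 0 & seg$start < seg$end),
             "segment with start >= end or negative start")
  check_that(all(seg$end <= chrom_length(dict, seg$chrom)),
             "segment beyond chromosome end")
  check_that(all(seg$minor_cn >= 0 & seg$major_cn >= seg$minor_cn),
             "segment with major_cn < minor_cn or negative minor_cn")
  check_that(all(abs(seg$total_cn - (seg$major_cn + seg$minor_cn)) <= 0.01),
             "segment with total_cn != major_cn + minor_cn")
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1) {
      bad <- which(s$start[-1] < s$end[-nrow(s)])
      if (length(bad)) {
        stop(sprintf(
          "overlapping segments on %s: [%d,%d) and [%d,%d)", ch,
          s$start[bad[1]], s$end[bad[1]],
          s$start[bad[1] + 1], s$end[bad[1] + 1]), call. = FALSE)
      }
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Validate a BAF site table
#' @inheritParams validate_segments
#' @param baf BAF data.frame.
#' @export
validate_baf <- function(baf, dict) {
  need <- c("chrom", "pos", "baf", "depth")
  check_that(all(need %in% names(baf)), "BAF table missing columns")
  if (nrow(baf) == 0) return(baf)
  check_that(all(baf$baf >= 0 & baf$baf <= 1), "BAF outside [0,1]")
  check_that(all(baf$depth >= 1), "BAF site with depth < 1")
  check_that(all(baf$pos >= 0 & baf$pos < chrom_length(dict, baf$chrom)),
             "BAF site off chromosome")
  baf[order(baf$chrom, baf$pos), , drop = FALSE]
}

#' Validate a structural-variant table
#' @inheritParams validate_segments
#' @param svs SV data.frame.
#' @export
validate_svs <- function(svs, dict) {
  need <- c("sv_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "svclass")
  check_that(all(need %in% names(svs)), "SV table missing columns")
  if (is.null(svs$inserted_seq)) svs$inserted_seq <- NA_character_
  if (nrow(svs) == 0) return(svs)
  check_that(all(svs$strand1 %in% c("+", "-") & svs$strand2 %in% c("+", "-")),
             "SV strand outside {+,-}")
  check_that(all(svs$svclass %in% sv_classes), "unknown svclass")
  cross <- svs$chrom1 != svs$chrom2
  check_that(all((svs$svclass == "BND") == cross),
             "svclass must be BND iff breakends are on different chromosomes")
  intra <- !cross
  check_that(all(svs$pos1[intra] <= svs$pos2[intra]),
             "intrachromosomal SV with pos1 > pos2")
  check_that(all(svs$pos1 >= 0 & svs$pos1 < chrom_length(dict, svs$chrom1)) &&
             all(svs$pos2 >= 0 & svs$pos2 < chrom_length(dict, svs$chrom2)),
             "SV breakend off chromosome")
  check_that(!anyDuplicated(svs$sv_id), "duplicated sv_id")
  rownames(svs) <- NULL
  svs
}

#' Validate a small-variant table
#' @inheritParams validate_segments
#' @param sv small-variant data.frame.
#' @export
validate_small_variants <- function(sv, dict) {
  need <- c("chrom", "pos", "ref", "alt", "vaf")
  check_that(all(need %in% names(sv)), "small-variant table missing columns")
  if (is.null(sv$gene)) sv$gene <- NA_character_
  if (is.null(sv$effect)) sv$effect <- NA_character_
  if (nrow(sv) == 0) return(sv)
  check_that(all(sv$vaf >= 0 & sv$vaf <= 1), "VAF outside [0,1]")
  check_that(all(sv$ref != sv$alt), "variant with ref == alt")
  check_that(all(sv$pos >= 0 & sv$pos < chrom_length(dict, sv$chrom)),
             "variant off chromosome")
  sv
}

#' Assemble a sample profile
#'
#' A profile bundles one tumour/normal pair's somatic evidence. All
#' component tables are validated against `dict` on construction; tumour
#' purity below `min_purity` (the cohort inclusion floor, default 20%)
#' is rejected.
#'
#' @param sample_id sample identifier.
#' @param cohort_label one of `TP53_AML`, `TP53_MDS`, `CBF_AML`, `other`.
#' @param segments,baf_sites,svs,small_variants component tables.
#' @param purity tumour cell fraction in (0, 1].
#' @param ploidy mean tumour copy number (> 0).
#' @param tumor_reads_path,normal_reads_path optional SAM paths.
#' @param dict reference dictionary (default [grch38_dict()]).
#' @param min_purity inclusion floor on purity.
#' @return object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, cohort_label = "other",
                           segments = NULL, baf_sites = NULL, svs = NULL,
                           small_variants = NULL, purity = 1, ploidy = 2,
                           tumor_reads_path = NA_character_,
                           normal_reads_path = NA_character_,
                           dict = grch38_dict(), min_purity = 0.2) {
  check_that(cohort_label %in% c("TP53_AML", "TP53_MDS", "CBF_AML", "other"),
             "unknown cohort label %s", cohort_label)
  check_that(purity > 0 && purity <= 1, "purity must be in (0,1]")
  check_that(purity >= min_purity,
             "sample %s purity %.2f below inclusion floor %.2f",
             sample_id, purity, min_purity)
  check_that(ploidy > 0, "ploidy must be positive")
  empty_seg <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), total_cn = numeric(),
                          major_cn = numeric(), minor_cn = numeric(),
                          log2_ratio = numeric())
  empty_baf <- data.frame(chrom = character(), pos = numeric(),
                          baf = numeric(), depth = numeric())
  empty_sv <- data.frame(sv_id = character(), chrom1 = character(),
                         pos1 = numeric(), strand1 = character(),
                         chrom2 = character(), pos2 = numeric(),
                         strand2 = character(), svclass = character(),
                         inserted_seq = character())
  empty_small <- data.frame(chrom = character(), pos = numeric(),
                            ref = character(), alt = character(),
                            vaf = numeric(), gene = character(),
                            effect = character())
  structure(list(
    sample_id = sample_id,
    cohort_label = cohort_label,
    segments = validate_segments(if (is.null(segments)) empty_seg else segments, dict),
    baf_sites = validate_baf(if (is.null(baf_sites)) empty_baf else baf_sites, dict),
    svs = validate_svs(if (is.null(svs)) empty_sv else svs, dict),
    small_variants = validate_small_variants(
      if (is.null(small_variants)) empty_small else small_variants, dict),
    purity = purity, ploidy = ploidy,
    tumor_reads_path = tumor_reads_path,
    normal_reads_path = normal_reads_path,
    dict = dict
  ), class = "sample_profile")
}

#' @exportS3Method base::print
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile %s [%s] purity=%.2f: %d segments, %d BAF sites, %d SVs, %d small variants>\n",
    x$sample_id, x$cohort_label, x$purity, nrow(x$segments),
    nrow(x$baf_sites), nrow(x$svs), nrow(x$small_variants)))
  invisible(x)
}

# ---------------------------------------------------------------- VCF ----

#' Read somatic small variants from a VCF
#'
#' Positions are converted from 1-based VCF to the package's 0-based
#' convention and multiallelic records are split into one row per ALT.
#' VAF is taken from the `AF` INFO tag when present, otherwise computed
#' from the first sample's `AD` pair; a record carrying neither is an
#' error. Optional `GENE` and `EFFECT` INFO tags populate the annotation
#' columns.
#'
#' @param path VCF 4.x text file.
#' @return small-variant data.frame (see [core_io]).
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first) || !grepl("^##fileformat=VCFv?4", first)) {
    stop(sprintf("malformed VCF header in %s", path), call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record drops dimensions
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      vaf = numeric(), gene = character(),
                      effect = character()))
  }
  info <- vcfR::getINFO(v)
  grab <- function(tag) {
    m <- regmatches(info, regexpr(sprintf("(^|;)%s=[^;]*", tag), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(sprintf("(^|;)%s=", tag), info)
    out[hit] <- sub(sprintf("^;?%s=", tag), "", m)
    out
  }
  af_raw <- grab("AF")
  gene_raw <- grab("GENE")
  eff_raw <- grab("EFFECT")
  ad_raw <- rep(NA_character_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    ad <- try(vcfR::extract.gt(v, element = "AD"), silent = TRUE)
    if (!inherits(ad, "try-error") && !is.null(ad)) ad_raw <- ad[, 1]
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (!is.na(af_raw[i])) {
      as.numeric(strsplit(af_raw[i], ",", fixed = TRUE)[[1]])
    }
    ads <- if (!is.na(ad_raw[i])) {
      as.numeric(strsplit(ad_raw[i], ",", fixed = TRUE)[[1]])
    }
    vafs <- numeric(length(alts))
    for (k in seq_along(alts)) {
      if (!is.null(afs) && length(afs) >= k && !is.na(afs[k])) {
        vafs[k] <- afs[k]
      } else if (!is.null(ads) && length(ads) >= k + 1) {
        vafs[k] <- ads[k + 1] / sum(ads)
      } else {
        stop(sprintf(
          "record %s:%s %s>%s carries neither AF nor AD; cannot recover VAF",
          fix$CHROM[i], fix$POS[i], fix$REF[i], fix$ALT[i]), call. = FALSE)
      }
    }
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]) - 1,
      ref = fix$REF[i], alt = alts, vaf = vafs,
      gene = if (is.na(gene_raw[i])) NA_character_ else gene_raw[i],
      effect = if (is.na(eff_raw[i])) NA_character_ else eff_raw[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write small variants to VCF
#'
#' Inverse of [read_vcf()]: emits VCF 4.2 with VAF in the `AF` INFO tag
#' (full precision, so write/read round-trips are exact) and annotation
#' in `GENE`/`EFFECT`.
#'
#' @param variants small-variant data.frame.
#' @param path output file.
#' @param dict reference dictionary for contig header lines.
#' @export
write_vcf <- function(variants, path, dict = grch38_dict()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", dict$chroms$chrom,
            dict$chroms$length),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Consequence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(variants)) {
    info <- sprintf("AF=%.10g", variants$vaf)
    has_gene <- !is.na(variants$gene)
    info[has_gene] <- paste0(info[has_gene], ";GENE=", variants$gene[has_gene])
    has_eff <- !is.na(variants$effect)
    info[has_eff] <- paste0(info[has_eff], ";EFFECT=", variants$effect[has_eff])
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    variants$chrom, as.integer(variants$pos + 1),
                    variants$ref, variants$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# -------------------------------------------------------------- BEDPE ----

#' Read structural variants from BEDPE
#'
#' Expects the 10-column BEDPE layout (`chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2`) with optional `svclass` and
#' `inserted_seq` columns 11-12. Coordinates are BEDPE 0-based half-open
#' and preserved as-is (`pos` = start of each breakend interval). When
#' the class column is absent it is inferred from the orientation pair:
#' `+/-` DEL, `-/+` DUP, `+/+` or `-/-` INV, cross-chromosome BND.
#'
#' @param path BEDPE file.
#' @return SV data.frame (see [core_io]).
#' @export
read_bedpe <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:12), fill = TRUE)
  if (nrow(raw) == 0 || all(is.na(raw$V1))) {
    return(validate_svs(data.frame(
      sv_id = character(), chrom1 = character(), pos1 = numeric(),
      strand1 = character(), chrom2 = character(), pos2 = numeric(),
      strand2 = character(), svclass = character(),
      inserted_seq = character()), toy_genome()))
  }
  check_that(all(raw$V9 %in% c("+", "-")) && all(raw$V10 %in% c("+", "-")),
             "BEDPE strand field outside {+,-}")
  svclass <- raw$V11
  need_infer <- is.na(svclass) | svclass == ""
  inferred <- ifelse(raw$V1 != raw$V4, "BND",
              ifelse(raw$V9 == "+" & raw$V10 == "-", "DEL",
              ifelse(raw$V9 == "-" & raw$V10 == "+", "DUP", "INV")))
  svclass[need_infer] <- inferred[need_infer]
  ins <- raw$V12
  ins[is.na(ins) | ins == ""] <- NA_character_
  data.frame(sv_id = as.character(raw$V7),
             chrom1 = raw$V1, pos1 = as.numeric(raw$V2), strand1 = raw$V9,
             chrom2 = raw$V4, pos2 = as.numeric(raw$V5), strand2 = raw$V10,
             svclass = svclass, inserted_seq = ins)
}

#' Write structural variants to BEDPE
#' @param svs SV data.frame.
#' @param path output file.
#' @export
write_bedpe <- function(svs, path) {
  if (nrow(svs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ins <- ifelse(is.na(svs$inserted_seq), "", svs$inserted_seq)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t%s\t%s\t%s\t%s",
                   svs$chrom1, as.integer(svs$pos1), as.integer(svs$pos1 + 1),
                   svs$chrom2, as.integer(svs$pos2), as.integer(svs$pos2 + 1),
                   svs$sv_id, svs$strand1, svs$strand2, svs$svclass, ins)
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------ TSVs -------

#' Read/write allele-specific copy-number segments (SEG-like TSV)
#'
#' Tab-separated with header
#' `chrom start end total_cn major_cn minor_cn log2_ratio`,
#' 0-based half-open.
#'
#' @param path TSV file.
#' @param dict reference dictionary used for validation.
#' @return segments data.frame.
#' @export
read_segments <- function(path, dict = grch38_dict()) {
  seg <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_segments(seg, dict)
}

#' @rdname read_segments
#' @param seg segments data.frame.
#' @export
write_segments <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write heterozygous-site BAF tracks
#'
#' Tab-separated with header `chrom pos baf depth` (0-based positions).
#'
#' @inheritParams read_segments
#' @export
read_baf <- function(path, dict = grch38_dict()) {
  baf <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_baf(baf, dict)
}

#' @rdname read_baf
#' @param baf BAF data.frame.
#' @export
write_baf <- function(baf, path) {
  utils::write.table(baf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------- SAM ----

#' Read aligned reads from text SAM
#'
#' Minimal-contract SAM consumption: header lines are skipped and the
#' eleven mandatory columns parsed. Returns one row per read with the
#' alignment position converted to 0-based.
#'
#' @param path SAM text file.
#' @return data.frame with `qname, flag, chrom, pos, mapq, cigar, seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = numeric(),
                      mapq = integer(), cigar = character(),
                      seq = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  check_that(all(lengths(parts) >= 11), "SAM line with fewer than 11 fields")
  m <- matrix(unlist(lapply(parts, `[`, 1:11)), ncol = 11, byrow = TRUE)
  data.frame(qname = m[, 1], flag = as.integer(m[, 2]), chrom = m[, 3],
             pos = as.numeric(m[, 4]) - 1, mapq = as.integer(m[, 5]),
             cigar = m[, 6], seq = m[, 10])
}

#' Write reads to text SAM
#'
#' @param reads data.frame as returned by [read_sam()].
#' @param path output file.
#' @param dict reference dictionary for `@SQ` header lines.
#' @export
write_sam <- function(reads, path, dict = toy_genome()) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", dict$chroms$chrom,
                   dict$chroms$length))
  body <- character(0)
  if (nrow(reads)) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                    reads$qname, reads$flag, reads$chrom,
                    as.integer(reads$pos + 1), reads$mapq, reads$cigar,
                    reads$seq)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a CIGAR string into operations
#'
#' @param cigar CIGAR string (or `"*"`).
#' @return data.frame with `len` and `op` columns.
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(), op = character()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  check_that(length(lens) == length(ops), "malformed CIGAR %s", cigar)
  data.frame(len = lens, op = ops)
}

#' Soft-clip lengths of a CIGAR
#'
#' @param cigar CIGAR string.
#' @return named numeric vector `c(left=, right=)` of soft-clipped bases.
#' @export
cigar_clips <- function(cigar) {
  ops <- cigar_ops(cigar)
  left <- if (nrow(ops) && ops$op[1] == "S") ops$len[1] else 0L
  right <- if (nrow(ops) > 1 && ops$op[nrow(ops)] == "S") {
    ops$len[nrow(ops)]
  } else if (nrow(ops) == 1 && ops$op[1] == "S") 0L else 0L
  c(left = left, right = right)
}

# ------------------------------------------------------ sample sheet -----

#' Read a cohort sample sheet
#'
#' Tab-separated with header `sample_id cohort_label purity ploidy
#' segments baf svs small_variants tumor_reads normal_reads`; file
#' columns are paths relative to the sheet's directory (`NA` or empty for
#' absent inputs). Each referenced file is loaded and validated, and
#' samples below the purity inclusion floor are rejected.
#'
#' @param path sample sheet TSV.
#' @param dict reference dictionary.
#' @param min_purity purity inclusion floor (default 0.2).
#' @return list of [sample_profile()] objects.
#' @export
read_sample_sheet <- function(path, dict = grch38_dict(), min_purity = 0.2) {
  sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.na(p)) NA_character_ else file.path(base, p)
  lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    load_or_null <- function(col, reader) {
      p <- resolve(row[[col]])
      if (is.na(p)) NULL else reader(p)
    }
    sample_profile(
      sample_id = row$sample_id,
      cohort_label = row$cohort_label,
      segments = load_or_null("segments", function(p) read_segments(p, dict)),
      baf_sites = load_or_null("baf", function(p) read_baf(p, dict)),
      svs = load_or_null("svs", function(p) read_bedpe(p)),
      small_variants = load_or_null("small_variants", read_vcf),
      purity = row$purity, ploidy = row$ploidy,
      tumor_reads_path = resolve(row$tumor_reads),
      normal_reads_path = resolve(row$normal_reads),
      dict = dict, min_purity = min_purity)
  })
}
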