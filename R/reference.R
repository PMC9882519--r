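#' Reference dictionaries
#'
#' All coordinates in the package are validated against a reference
#' dictionary: a set of chromosome names and lengths, optionally with
#' named p/q arms. Two dictionaries ship with the package -- the GRCh38
#' primary chromosomes for real call sets, and a small 4-chromosome toy
#' genome used by the synthetic cohort generator so that whole-cohort
#' simulation runs in seconds.
#'
#' @param chroms data.frame with columns `chrom`, `length` and logical
#'   `autosome`.
#' @param arms optional data.frame with columns `chrom`, `arm` (`"p"` or
#'   `"q"`), `start`, `end` (0-based half-open).
#' @return an object of class `ref_dict`.
#' @export
reference_dict <- function(chroms, arms = NULL) {
  check_that(all(c("chrom", "length") %in% names(chroms)),
             "reference dictionary needs chrom and length columns")
  if (is.null(chroms$autosome)) chroms$autosome <- TRUE
  check_that(!anyDuplicated(chroms$chrom), "duplicated chromosome names")
  check_that(all(chroms$length > 0), "chromosome lengths must be positive")
  if (!is.null(arms)) {
    check_that(all(arms$chrom %in% chroms$chrom),
               "arm table names a chromosome absent from the dictionary")
  }
  structure(list(chroms = chroms, arms = arms), class = "ref_dict")
}

#' @exportS3Method base::print
print.ref_dict <- function(x, ...) {
  cat(sprintf("<ref_dict: %d chromosomes, %s arms>\n",
              nrow(x$chroms),
              if (is.null(x$arms)) "no" else nrow(x$arms)))
  invisible(x)
}

#' @rdname reference_dict
#' @export
chrom_length <- function(dict, chrom) {
  i <- match(chrom, dict$chroms$chrom)
  check_that(!anyNA(i), "chromosome %s not in reference dictionary",
             paste(unique(chrom[is.na(i)]), collapse = ","))
  dict$chroms$length[i]
}

#' GRCh38 primary-chromosome dictionary
#'
#' Chromosome names and lengths of the GRCh38 primary assembly with
#' cytogenetic arm boundaries approximated by centromere midpoints.
#'
#' @return a `ref_dict`.
#' @export
grch38_dict <- function() {
  chrom <- paste0("chr", c(1:22, "X", "Y"))
  len <- c(248956422, 242193529, 198295559, 190214555, 181538259,
           170805979, 159345973, 145138636, 138394717, 133797422,
           135086622, 133275309, 114364328, 107043718, 101991189,
           90338345, 83257441, 80373285, 58617616, 64444167,
           46709983, 50818468, 156040895, 57227415)
  cen <- c(123400000, 93900000, 90900000, 50000000, 48800000,
           59800000, 60100000, 45200000, 43000000, 39800000,
           53400000, 35500000, 17700000, 17200000, 19000000,
           36800000, 25100000, 18500000, 26200000, 28100000,
           12000000, 15000000, 61000000, 10400000)
  chroms <- data.frame(chrom = chrom, length = len,
                       autosome = !(chrom %in% c("chrX", "chrY")))
  arms <- rbind(
    data.frame(chrom = chrom, arm = "p", start = 0, end = cen),
    data.frame(chrom = chrom, arm = "q", start = cen, end = len)
  )
  reference_dict(chroms, arms)
}

#' Toy genome for desk-scale simulation
#'
#' Four autosomes (50, 40, 25 and 10 Mb) with named arms. The synthetic
#' cohort generator plants its recurrent events on these arms:
#' `chrT1q` carries the most frequent arm loss (emulating 5q), `chrT2q` a
#' second recurrent loss (7q-like), `chrT3p` hosts the TP53 locus
#' (17p-like) and `chrT4p` hosts the focal-deletion target region with
#' its minimally-deleted core (12p-like).
#'
#' @return a `ref_dict`.
#' @export
toy_genome <- function() {
  chroms <- data.frame(
    chrom = c("chrT1", "chrT2", "chrT3", "chrT4"),
    length = c(50e6, 40e6, 25e6, 10e6),
    autosome = TRUE
  )
  cen <- c(20e6, 15e6, 10e6, 4e6)
  arms <- rbind(
    data.frame(chrom = chroms$chrom, arm = "p", start = 0, end = cen),
    data.frame(chrom = chroms$chrom, arm = "q", start = cen,
               end = chroms$length)
  )
  reference_dict(chroms, arms)
}

#' Arm interval lookup
#'
#' @param dict a `ref_dict` with an arm table.
#' @param arm_name arm as `"<chrom><p|q>"`, e.g. `"chrT1q"`.
#' @return list with `chrom`, `start`, `end`.
#' @export
arm_interval <- function(dict, arm_name) {
  check_that(!is.null(dict$arms), "dictionary has no arm table")
  a <- substring(arm_name, nchar(arm_name))
  ch <- substring(arm_name, 1, nchar(arm_name) - 1)
  row <- dict$arms[dict$arms$chrom == ch & dict$arms$arm == a, ]
  check_that(nrow(row) == 1, "unknown arm %s", arm_name)
  list(chrom = ch, start = row$start, end = row$end)
}

#' Synthetic gene annotation for the toy genome
#'
#' Gene bodies used by landscape and minimally-deleted-region analyses of
#' simulated cohorts. Real gene symbols are used as labels for
#' readability (TP53 on chrT3p, and an 18-gene block including ETV6 and
#' CDKN1B inside the plantable deletion core on chrT4p), but the
#' coordinates are synthetic toy-genome positions.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open).
#' @export
toy_gene_annotation <- function() {
  core <- mdr_core_default()
  n_core <- 18L
  width <- 60e3
  starts <- seq(core$start + 2e4, core$end - width - 2e4,
                length.out = n_core)
  core_genes <- data.frame(
    chrom = "chrT4",
    start = round(starts),
    end = round(starts) + width,
    gene = c("ETV6", "CDKN1B", paste0("G12P_", sprintf("%02d", 3:n_core)))
  )
  other <- data.frame(
    chrom = c("chrT3", "chrT3", "chrT1", "chrT2"),
    start = c(7.0e6, 16.0e6, 35.0e6, 30.0e6),
    end   = c(7.02e6, 16.1e6, 35.1e6, 30.1e6),
    gene = c("TP53", "NF1", "GENE_T1Q", "GENE_T2Q")
  )
  rbind(core_genes, other)
}

#' Default minimally-deleted core on the toy genome
#'
#' The 2.75-Mb interval on chrT4p that simulated focal deletions share.
#'
#' @return list with `chrom`, `start`, `end`.
#' @export
mdr_core_default <- function() {
  list(chrom = "chrT4", start = 6e5, end = 6e5 + 2.75e6)
}

#' Default TP53-like locus on the toy genome
#'
#' A 20-kb locus on chrT3p standing in for TP53 (whose GRCh38 locus is
#' chr17:7668401-7687549; use that interval with [grch38_dict()] for real
#' call sets).
#'
#' @return list with `chrom`, `start`, `end`, `gene`.
#' @export
tp53_locus_toy <- function() {
  list(chrom = "chrT3", start = 7.0e6, end = 7.02e6, gene = "TP53")
}
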