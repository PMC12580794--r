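#' @title Data model: variants, segments, samples, genes, cohorts
#'
#' @description
#' The pipeline works on four plain data.frames plus a cohort container:
#' \itemize{
#'   \item variants: one row per somatic variant observed in one sample
#'     (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `alt_depth`, `ref_depth`,
#'     `vaf`, `gene`, `consequence`). Absence of a row means the variant was
#'     not observed in that sample; an observation requires `alt_depth >= 2`
#'     to count as present (sequencing-error guard at high depth).
#'   \item segments: one absolute copy-number segment per row (`sample_id`,
#'     `chrom`, `start`, `end`, `total_cn`, `minor_cn`), 1-based closed
#'     coordinates, non-overlapping within a sample.
#'   \item samples: the sample sheet (`patient_id`, `sample_id`,
#'     `tissue_site`, `purity`, `ploidy`, `sex`).
#'   \item genes: gene intervals (`gene`, `chrom`, `start`, `end`).
#' }
#' All coordinates are 1-based closed internally; BED input is converted on
#' read. Chromosome names are normalized to the `chr` prefix.
#' @name clonemap-data-model
NULL

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                  "synonymous", "other")

#' Construct and validate a variant table
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_depth`, `ref_depth`, and optionally `gene`, `consequence`.
#' @return Validated variant data.frame with normalized chromosomes and a
#'   `vaf` column (`alt_depth / (alt_depth + ref_depth)`).
#' @export
as_variant_table <- function(df) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "alt_depth", "ref_depth")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("variant table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) df$gene <- ""
  if (!"consequence" %in% names(df)) df$consequence <- "other"
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$alt_depth <- as.integer(df$alt_depth)
  df$ref_depth <- as.integer(df$ref_depth)
  depth <- df$alt_depth + df$ref_depth
  bad <- which(is.na(depth) | depth <= 0 | df$alt_depth < 0 | df$ref_depth < 0)
  if (length(bad) > 0)
    stop("invalid read depths (alt_depth + ref_depth must be > 0) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(is.na(df$pos) | df$pos < 1))
    stop("invalid variant position at row(s): ",
         paste(utils::head(which(is.na(df$pos) | df$pos < 1), 5), collapse = ", "))
  badc <- !df$consequence %in% CONSEQUENCES
  if (any(badc)) df$consequence[badc] <- "other"
  df$vaf <- df$alt_depth / depth
  df$gene[is.na(df$gene)] <- ""
  rownames(df) <- NULL
  df[c("sample_id", "chrom", "pos", "ref", "alt", "alt_depth", "ref_depth",
       "vaf", "gene", "consequence")]
}

#' Variant key (patient-level identity of a mutation)
#'
#' @param variants Variant table.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Read somatic variants from TSV or VCF
#'
#' The TSV dialect is MAF-like with header columns `sample`, `chrom`, `pos`,
#' `ref`, `alt`, `alt_depth`, `ref_depth`, `gene`, `consequence`. The VCF
#' reader (v4.x) takes per-sample depths from the `AD` FORMAT field and gene /
#' consequence annotations from `GENE=` / `CSQ=` INFO keys when present; a
#' sample column with missing or all-reference `AD` contributes no record.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return Variant table (see [as_variant_table()]).
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "")
    req <- c("sample", "chrom", "pos", "ref", "alt", "alt_depth", "ref_depth")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0)
      stop("variant TSV ", path, " is missing columns: ",
           paste(miss, collapse = ", "))
    num <- suppressWarnings(list(pos = as.integer(df$pos),
                                 ad = as.integer(df$alt_depth),
                                 rd = as.integer(df$ref_depth)))
    badrow <- which(is.na(num$pos) | is.na(num$ad) | is.na(num$rd))
    if (length(badrow) > 0)
      stop("malformed variant row at line ", badrow[1] + 1L, " of ", path)
    names(df)[names(df) == "sample"] <- "sample_id"
    return(as_variant_table(df))
  }
  .read_variants_vcf(path)
}

.read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  fmt <- v@gt
  if (is.null(fmt) || ncol(fmt) < 2) stop("VCF ", path, " has no sample columns")
  if (!any(grepl("AD", fmt[, "FORMAT"])))
    stop("VCF ", path, " has no AD field; per-sample depths unavailable")
  info <- fix$INFO
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    has <- grepl(paste0(key, "="), info)
    out <- rep("", length(info))
    out[has] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  gene <- get_info("GENE")
  csq <- get_info("CSQ")
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  recs <- lapply(samples, function(s) {
    x <- ad[, s]
    keep <- !is.na(x) & x != "." & x != ""
    if (!any(keep)) return(NULL)
    parts <- strsplit(x[keep], ",", fixed = TRUE)
    rd <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    adep <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    pos_alt <- adep > 0
    if (!any(pos_alt)) return(NULL)
    idx <- which(keep)[pos_alt]
    data.frame(sample_id = s, chrom = fix$CHROM[idx],
               pos = as.integer(fix$POS[idx]), ref = fix$REF[idx],
               alt = fix$ALT[idx], alt_depth = adep[pos_alt],
               ref_depth = rd[pos_alt], gene = gene[idx],
               consequence = csq[idx], stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) stop("VCF ", path, " contains no variant observations")
  recs$consequence[recs$consequence == ""] <- "other"
  as_variant_table(recs)
}

#' Write somatic variants to TSV or VCF
#'
#' @param variants Variant table.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  variants <- as_variant_table(variants)
  if (format == "tsv") {
    out <- variants[c("sample_id", "chrom", "pos", "ref", "alt",
                      "alt_depth", "ref_depth", "gene", "consequence")]
    names(out)[1] <- "sample"
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  .write_variants_vcf(variants, path)
}

.write_variants_vcf <- function(variants, path) {
  key <- variant_key(variants)
  samples <- sort(unique(variants$sample_id))
  uk <- !duplicated(key)
  site <- variants[uk, c("chrom", "pos", "ref", "alt", "gene", "consequence")]
  site_key <- key[uk]
  o <- order(site$chrom, site$pos, site$ref, site$alt)
  site <- site[o, ]; site_key <- site_key[o]
  gt <- matrix(".", nrow = nrow(site), ncol = length(samples),
               dimnames = list(site_key, samples))
  idx <- cbind(match(key, site_key), match(variants$sample_id, samples))
  gt[idx] <- paste0(variants$ref_depth, ",", variants$alt_depth)
  info <- paste0("GENE=", site$gene, ";CSQ=", site$consequence)
  body <- paste(site$chrom, site$pos, ".", site$ref, site$alt, ".", "PASS",
                info, "AD", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Ref,alt read depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct and validate a copy-number segment table
#'
#' Segments are 1-based closed, sorted, and must not overlap within a
#' sample/chromosome; `minor_cn` must be at most `total_cn - minor_cn`.
#'
#' @param df data.frame with `sample_id`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`.
#' @return Validated segment table with a `length` column.
#' @export
as_segment_table <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("segment table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- normalize_chrom(df$chrom)
  for (col in c("start", "end", "total_cn", "minor_cn"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start))
    stop("invalid segment coordinates at row(s): ",
         paste(utils::head(which(is.na(df$start) | is.na(df$end) |
                                   df$start < 1 | df$end < df$start), 5),
               collapse = ", "))
  if (any(is.na(df$total_cn) | df$total_cn < 0))
    stop("total_cn must be a non-negative integer")
  if (any(is.na(df$minor_cn) | df$minor_cn < 0))
    stop("minor_cn must be a non-negative integer")
  bad <- df$minor_cn > df$total_cn - df$minor_cn
  if (any(bad))
    stop("minor_cn exceeds major allele count at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  df <- df[order(df$sample_id, df$chrom, df$start), ]
  rownames(df) <- NULL
  by_sc <- split(seq_len(nrow(df)), paste(df$sample_id, df$chrom))
  for (idx in by_sc) {
    if (length(idx) < 2) next
    s <- df$start[idx]; e <- df$end[idx]
    ov <- which(s[-1] <= e[-length(e)])
    if (length(ov) > 0)
      stop("overlapping segments in sample ", df$sample_id[idx[1]], " ",
           df$chrom[idx[1]], ": [", s[ov[1]], "-", e[ov[1]], "] and [",
           s[ov[1] + 1], "-", e[ov[1] + 1], "]")
  }
  df$length <- df$end - df$start + 1
  df[c("sample_id", "chrom", "start", "end", "total_cn", "minor_cn", "length")]
}

#' Read copy-number segments (SEG/TSV dialect)
#'
#' Expects header columns `sample`, `chrom`, `start`, `end`, `total_cn`,
#' `minor_cn` (IGV SEG extended with allele-specific copy number).
#'
#' @param path File path.
#' @return Validated segment table.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("segment file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  names(df)[names(df) == "sample"] <- "sample_id"
  as_segment_table(df)
}

#' Write copy-number segments
#'
#' @param segments Segment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  segments <- as_segment_table(segments)
  out <- segments[c("sample_id", "chrom", "start", "end", "total_cn",
                    "minor_cn")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  names(out)[1] <- "sample"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' @param df data.frame with `patient_id`, `sample_id`, `tissue_site`,
#'   `purity`, `ploidy`, `sex`.
#' @return Validated sample sheet; `sex` is checked against
#'   `c("male", "female")`, purity must be in (0, 1].
#' @export
as_sample_sheet <- function(df) {
  req <- c("patient_id", "sample_id", "tissue_site", "purity", "ploidy", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$purity <- as.numeric(df$purity)
  df$ploidy <- as.numeric(df$ploidy)
  if (any(is.na(df$purity) | df$purity <= 0 | df$purity > 1))
    stop("purity must lie in (0, 1]; offending sample(s): ",
         paste(df$sample_id[is.na(df$purity) | df$purity <= 0 |
                              df$purity > 1], collapse = ", "))
  if (any(is.na(df$ploidy) | df$ploidy <= 0))
    stop("ploidy must be positive")
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  rownames(df) <- NULL
  df[req]
}

#' Read the sample sheet
#'
#' TSV with header `patient`, `sample`, `site`, `purity`, `ploidy`, `sex`.
#'
#' @param path File path.
#' @return Validated sample sheet.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  ren <- c(patient = "patient_id", sample = "sample_id", site = "tissue_site")
  for (nm in names(ren)) names(df)[names(df) == nm] <- ren[[nm]]
  as_sample_sheet(df)
}

#' Write the sample sheet
#'
#' @param samples Sample sheet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  samples <- as_sample_sheet(samples)
  out <- samples
  names(out) <- c("patient", "sample", "site", "purity", "ploidy", "sex")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; coordinates are converted to the internal
#' 1-based closed convention (`start + 1`, `end` unchanged). The fourth BED
#' column is the gene name.
#'
#' @param path BED file path.
#' @return data.frame `gene`, `chrom`, `start`, `end` (1-based closed).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file ", path, " needs 4 columns (chrom, start, end, name)")
  out <- data.frame(gene = df[[4]], chrom = normalize_chrom(df[[1]]),
                    start = as.numeric(df[[2]]) + 1, end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("BED file ", path, " has empty intervals")
  if (anyDuplicated(out$gene))
    stop("duplicated gene names in ", path)
  out
}

#' Write gene intervals to BED
#'
#' @param genes Gene interval table (1-based closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom,
                    start = format(genes$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(genes$end, scientific = FALSE, trim = TRUE),
                    name = genes$gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a patient cohort
#'
#' Bundles the sample sheet, variants, segments and (optionally) recurrent
#' loci, enforcing referential integrity: every variant and segment
#' `sample_id` must resolve to a sample-sheet row.
#'
#' @param samples Sample sheet.
#' @param variants Variant table.
#' @param segments Segment table.
#' @param recurrent_loci Optional gene-interval table with a `direction`
#'   column (`"amp"` or `"del"`).
#' @return An object of class `patient_cohort`.
#' @export
patient_cohort <- function(samples, variants, segments, recurrent_loci = NULL) {
  samples <- as_sample_sheet(samples)
  variants <- as_variant_table(variants)
  segments <- as_segment_table(segments)
  orphan_v <- setdiff(unique(variants$sample_id), samples$sample_id)
  if (length(orphan_v) > 0)
    stop("variants reference unknown sample(s): ",
         paste(orphan_v, collapse = ", "))
  orphan_s <- setdiff(unique(segments$sample_id), samples$sample_id)
  if (length(orphan_s) > 0)
    stop("segments reference unknown sample(s): ",
         paste(orphan_s, collapse = ", "))
  structure(list(samples = samples, variants = variants, segments = segments,
                 recurrent_loci = recurrent_loci),
            class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat("patient_cohort:", length(unique(x$samples$patient_id)), "patient(s),",
      nrow(x$samples), "sample(s),", nrow(x$variants), "variant record(s),",
      nrow(x$segments), "segment(s)\n")
  invisible(x)
}

#' Subset a cohort to one patient
#'
#' @param cohort `patient_cohort`.
#' @param patient_id Patient identifier.
#' @return `patient_cohort` restricted to that patient's samples.
#' @export
cohort_patient <- function(cohort, patient_id) {
  keep <- cohort$samples$patient_id == patient_id
  if (!any(keep)) stop("unknown patient: ", patient_id)
  ids <- cohort$samples$sample_id[keep]
  patient_cohort(cohort$samples[keep, , drop = FALSE],
                 cohort$variants[cohort$variants$sample_id %in% ids, , drop = FALSE],
                 cohort$segments[cohort$segments$sample_id %in% ids, , drop = FALSE],
                 cohort$recurrent_loci)
}

#' Read a cohort from a directory of standard files
#'
#' Expects `samples.tsv`, `variants.tsv` (or `variants.vcf`), `segments.seg`,
#' and optionally `genes.bed` as written by [simulate_cohort()] or
#' [write_cohort()].
#'
#' @param dir Directory path.
#' @return `patient_cohort`.
#' @export
read_cohort <- function(dir) {
  vpath <- file.path(dir, "variants.tsv")
  if (!file.exists(vpath)) vpath <- file.path(dir, "variants.vcf")
  cohort <- patient_cohort(
    read_sample_sheet(file.path(dir, "samples.tsv")),
    read_variants(vpath),
    read_segments(file.path(dir, "segments.seg"))
  )
  gpath <- file.path(dir, "genes.bed")
  if (file.exists(gpath)) cohort$genes <- read_gene_bed(gpath)
  cohort
}

#' Write a cohort to a directory of standard files
#'
#' @param cohort `patient_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  if (!is.null(cohort$genes))
    write_gene_bed(cohort$genes, file.path(dir, "genes.bed"))
  invisible(dir)
}
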