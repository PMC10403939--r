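#' Read and write FASTA contigs
#'
#' Thin wrappers around Biostrings; sequences travel as a two-column tibble
#' (`contig_id`, `sequence`) so they pipe into [compute_gc()] and friends.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with `contig_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig_id = names(x), sequence = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param contigs Tibble with `contig_id` and `sequence` columns.
#' @param width Line-wrap width in the written file.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$contig_id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BLAST tabular hit file with subject taxids
#'
#' Expects the 13-column outfmt-6 dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore staxids` with no header.  Column count is validated;
#' multi-valued `staxids` keep the first taxid.
#'
#' @param path File path.
#' @return A homology-hit tibble: `query_id`, `subject_id`,
#'   `subject_taxon`, `evalue`, `bitscore`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "staxids")
  raw <- readr::read_tsv(path, col_names = cols,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  probe <- readr::problems(raw)
  if (nrow(probe) > 0 || ncol(raw) != 13)
    abort(sprintf("malformed BLAST tabular file '%s': expected 13 tab-separated columns", path),
          class = "viraltriage_format_error")
  out <- tibble(
    query_id = raw$qseqid,
    subject_id = raw$sseqid,
    subject_taxon = as.integer(sub(";.*$", "", raw$staxids)),
    evalue = as.numeric(raw$evalue),
    bitscore = as.numeric(raw$bitscore)
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0))
    abort(sprintf("malformed BLAST tabular file '%s': non-numeric or negative E-values", path),
          class = "viraltriage_format_error")
  out
}

#' Read a taxid-to-category map
#'
#' Two-column TSV `taxid<TAB>category` with header; categories are the
#' triage strata `viral`, `eukaryote_braconid`, `eukaryote_other`,
#' `bacterial`, `other`.
#'
#' @param path File path.
#' @return A tibble with `taxid` (integer) and `category`.
#' @export
read_taxon_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    taxid = readr::col_integer(), category = readr::col_character()
  ), progress = FALSE)
  valid <- c("viral", "eukaryote_braconid", "eukaryote_other", "bacterial", "other")
  bad <- setdiff(unique(x$category), valid)
  if (length(bad) > 0)
    abort(sprintf("unknown taxon categories in '%s': %s", path,
                  paste(bad, collapse = ", ")),
          class = "viraltriage_format_error")
  if (anyDuplicated(x$taxid))
    abort(sprintf("duplicate taxids in '%s'", path), class = "viraltriage_format_error")
  x
}

#' Read gene loci from a GFF3 file
#'
#' Keeps `gene`-type features only; the gene identifier is the `ID`
#' attribute.  Parsing is delegated to rtracklayer.
#'
#' @param path File path.
#' @return A gene-locus tibble: `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("read_gff_genes() requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr[gr$type == "gene"])
  tibble(
    gene_id = as.character(df$ID),
    contig_id = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
}

#' Read and write Hi-C contact pair tables
#'
#' Three-column TSV `contig_a<TAB>contig_b<TAB>count` with header.
#'
#' @param path File path.
#' @return `read_hic_pairs()`: tibble with `contig_a`, `contig_b`,
#'   integer `count`.
#' @export
read_hic_pairs <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig_a = readr::col_character(), contig_b = readr::col_character(),
    count = readr::col_integer()
  ), progress = FALSE)
  if (any(x$count < 1))
    abort(sprintf("Hi-C pair counts must be >= 1 in '%s'", path),
          class = "viraltriage_format_error")
  x
}

#' @rdname read_hic_pairs
#' @param pairs Pair tibble as returned by [simulate_hic_pairs()].
#' @export
write_hic_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Three-column TSV `sequence_id<TAB>pos<TAB>depth` with header, 1-based
#' positions (the `samtools depth -a` convention, plus a header).
#'
#' @param path File path.
#' @return A tibble with `sequence_id`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence_id = readr::col_character(), pos = readr::col_integer(),
    depth = readr::col_integer()
  ), progress = FALSE)
}

#' Read contig metrics
#'
#' Five-column TSV `contig_id length gc mean_depth group` with header;
#' `group` is `viral` or `reference`.
#'
#' @param path File path.
#' @return A contig-metrics tibble.
#' @export
read_contig_metrics <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig_id = readr::col_character(), length = readr::col_integer(),
    gc = readr::col_double(), mean_depth = readr::col_double(),
    group = readr::col_character()
  ), progress = FALSE)
}

#' Read profile-search (HMMER-style) hits
#'
#' Two dialects: `tblout` (whitespace-delimited HMMER `--tblout` layout,
#' `#`-comment lines skipped; target in column 1, query model in column 3,
#' full-sequence E-value and score in columns 5-6) and `tsv` (a simple
#' 5-column headered TSV `model_id target_id taxon_id evalue score`).
#'
#' @param path File path.
#' @param dialect `"tblout"` or `"tsv"`.
#' @param taxon_id For `tblout`, the assembly/species label to attach
#'   (tblout files are per-proteome and carry no taxon column).
#' @return A profile-hit tibble: `model_id`, `target_id`, `taxon_id`,
#'   `evalue`, `score`.
#' @export
read_profile_hits <- function(path, dialect = c("tsv", "tblout"), taxon_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- readr::read_tsv(path, col_types = readr::cols(
      model_id = readr::col_character(), target_id = readr::col_character(),
      taxon_id = readr::col_character(), evalue = readr::col_double(),
      score = readr::col_double()
    ), progress = FALSE)
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    keep <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    fields <- strsplit(trimws(keep), "\\s+")
    short <- which(lengths(fields) < 6)
    if (length(short) > 0)
      abort(sprintf("malformed tblout row at data line %d of '%s'", short[1], path),
            class = "viraltriage_format_error")
    out <- tibble(
      model_id = vapply(fields, `[[`, "", 3),
      target_id = vapply(fields, `[[`, "", 1),
      taxon_id = taxon_id %||% NA_character_,
      evalue = as.numeric(vapply(fields, `[[`, "", 5)),
      score = as.numeric(vapply(fields, `[[`, "", 6))
    )
  }
  if (any(is.na(out$evalue)) || any(out$evalue < 0))
    abort(sprintf("malformed profile hits in '%s': bad E-values", path),
          class = "viraltriage_format_error")
  out
}

#' Read VCF records into the flat record table used by [hard_filter()]
#'
#' Parsing is delegated to vcfR; the INFO keys QD, SOR, FS, MQ, MQRankSum
#' and ReadPosRankSum plus the first sample's AD are lifted into columns.
#' Missing annotations become `NA` (which [hard_filter()] treats as
#' passing, the GATK convention).
#'
#' @param path VCF 4.2 file path.
#' @return A record tibble matching [simulate_vcf()]'s layout (without the
#'   truth columns).
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = numeric(),
                  qd = numeric(), sor = numeric(), fs = numeric(), mq = numeric(),
                  mq_rank_sum = numeric(), read_pos_rank_sum = numeric(),
                  ad_ref = integer(), ad_alt = integer()))
  }
  info_num <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
  ad <- if (ncol(v@gt) >= 2) unname(vcfR::extract.gt(v, "AD")[, 1]) else rep(NA_character_, nrow(fix))
  ad_parts <- strsplit(ifelse(is.na(ad), "", ad), ",")
  ad_ref <- vapply(ad_parts, function(x) if (length(x) >= 1) suppressWarnings(as.integer(x[1])) else NA_integer_, integer(1))
  ad_alt <- vapply(ad_parts, function(x) if (length(x) >= 2) as.integer(sum(as.numeric(x[-1]))) else NA_integer_, integer(1))
  tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID %||% ".",
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = info_num("QD"), sor = info_num("SOR"), fs = info_num("FS"),
    mq = info_num("MQ"), mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    ad_ref = ad_ref, ad_alt = ad_alt
  )
}

#' Write a record table as VCF 4.2
#'
#' Emits the header lines for the INFO/FORMAT keys this package uses and
#' one pooled sample with GT:AD.  Intended for synthetic call sets from
#' [simulate_vcf()]; round-trips through [read_vcf_records()].
#'
#' @param records Record tibble (truth columns, if present, are ignored).
#' @param path Output path.
#' @param ploidy Ploidy of the pooled sample's written genotype.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, ploidy = 5L, sample_name = "pool") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=viraltriage",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio of strand bias">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias phred p">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  fmt1 <- function(x) ifelse(is.na(x), ".", formatC(x, format = "f", digits = 3))
  body <- if (nrow(records) > 0) {
    info <- sprintf("QD=%s;SOR=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s",
                    fmt1(records$qd), fmt1(records$sor), fmt1(records$fs),
                    fmt1(records$mq), fmt1(records$mq_rank_sum),
                    fmt1(records$read_pos_rank_sum))
    gt <- paste(rep("0", ploidy), collapse = "/")
    paste(records$chrom, records$pos, records$id %||% ".", records$ref,
          records$alt, fmt1(records$qual), ".", info, "GT:AD",
          sprintf("%s:%d,%d", gt, records$ad_ref, records$ad_alt), sep = "\t")
  } else character(0)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
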