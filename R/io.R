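# Table readers/writers share one engine: schema-versioned CSV with "." as
# the missing-value token and a comment header naming the schema.

TABLE_SCHEMAS <- list(
  survey = list(required = c("site_id", "plant_id", "flower_id", "bact_cfu",
                             "yeast_cfu"),
                optional = c("bact_effort", "yeast_effort")),
  ph = list(required = "ph",
            optional = c("site_id", "flower_id", "stigma", "anther")),
  growth = list(required = c("treatment", "focal_cfu"),
                optional = c("strain", "evolution_treatment", "round",
                             "replicate")),
  sample_meta = list(required = c("sample_id", "is_ancestor"),
                     optional = c("treatment", "lineage"))
)

#' Write a pipeline table as schema-versioned CSV
#'
#' UTF-8 CSV with a `# nectarpe table: <name> v1` comment header and `.` as
#' the missing-value token.
#'
#' @param x data frame.
#' @param path output path.
#' @param schema one of `"survey"`, `"ph"`, `"growth"`, `"sample_meta"`.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, schema = names(TABLE_SCHEMAS)) {
  schema <- match.arg(schema)
  spec <- TABLE_SCHEMAS[[schema]]
  missing_cols <- setdiff(spec$required, names(x))
  if (length(missing_cols) > 0) {
    stop_input("missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# nectarpe table: %s v1", schema), con)
  write.csv(x, con, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a pipeline table
#'
#' Validates the schema: missing required columns are an error; unknown
#' columns produce a warning and are kept.
#'
#' @param path CSV path.
#' @param schema table schema name.
#' @return data frame.
#' @export
read_table_csv <- function(path, schema = names(TABLE_SCHEMAS)) {
  schema <- match.arg(schema)
  spec <- TABLE_SCHEMAS[[schema]]
  x <- read.csv(path, comment.char = "#", na.strings = ".",
                stringsAsFactors = FALSE)
  missing_cols <- setdiff(spec$required, names(x))
  if (length(missing_cols) > 0) {
    stop_input("file ", path, " is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(x), c(spec$required, spec$optional))
  if (length(unknown) > 0) {
    warning("unknown column(s) in ", path, ": ",
            paste(unknown, collapse = ", "))
  }
  if (schema == "survey") {
    if (any(is.na(x$bact_cfu) | is.na(x$yeast_cfu)) ||
        any(x$bact_cfu < 0 | x$yeast_cfu < 0)) {
      stop_input("survey CFU counts must be present and non-negative")
    }
  }
  if (schema == "growth") {
    x$treatment <- gsub("−", "-", x$treatment)  # unicode minus
    bad <- which(!(x$treatment %in% GROWTH_TREATMENTS))
    if (length(bad) > 0) {
      stop_input("invalid treatment code in row ", bad[1], ": '",
                 x$treatment[bad[1]], "'")
    }
  }
  if (schema == "sample_meta") {
    x$is_ancestor <- as.logical(x$is_ancestor)
  }
  x
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 (plain or gzipped) with vcfR and maps GT calls to
#' genotype codes: `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`, `./. -> NA`;
#' phased separators are accepted. Records must be position-sorted within
#' chromosome; multiallelic records are skipped with a diagnostic (attribute
#' `n_multiallelic`). A record without GT is a format error.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || !"FORMAT" %in% colnames(gt_raw)) {
    stop_input("VCF has no genotype (FORMAT/GT) section: ", path)
  }
  no_gt <- !grepl("(^|:)GT(:|$)", gt_raw[, "FORMAT"])
  if (any(no_gt)) {
    stop_input("VCF record without GT at ", fix$CHROM[no_gt][1], ":",
               fix$POS[no_gt][1])
  }
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message("skipping ", n_multi, " multiallelic record(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt_raw <- gt_raw[!multi, , drop = FALSE]
  }
  samples <- setdiff(colnames(gt_raw), "FORMAT")
  gt <- sub(":.*$", "", gt_raw[, samples, drop = FALSE])
  gt <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- GT_HOM_REF
  code[gt %in% c("0/1", "1/0")] <- GT_HET
  code[gt == "1/1"] <- GT_HOM_ALT
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(!known)) {
    stop_input("unsupported GT value '", gt[!known][1], "' in ", path)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      bad <- which(diff(p) <= 0)[1] + 1
      stop_input("VCF not position-sorted at ", ch, ":", p[bad])
    }
  }
  gm <- genotype_matrix(sites, samples, code)
  attr(gm, "n_multiallelic") <- n_multi
  gm
}

#' Write a genotype matrix as a minimal GT-only VCF v4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @param contig_lengths optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=nectarpe", con)
  chroms <- unique(gm$sites$chrom)
  for (ch in chroms) {
    len <- if (!is.null(contig_lengths) && ch %in% names(contig_lengths)) {
      sprintf(",length=%d", as.integer(contig_lengths[[ch]]))
    } else ""
    writeLines(sprintf("##contig=<ID=%s%s>", ch, len), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  gt_str <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt_str[gm$geno == GT_HOM_REF] <- "0/0"
  gt_str[gm$geno == GT_HET] <- "0/1"
  gt_str[gm$geno == GT_HOM_ALT] <- "1/1"
  lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                 gm$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read/write a mappability track (bedGraph, 0-based half-open)
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`, `score`.
#' @export
read_mappability_bed <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "score"))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    stop_input("malformed BED interval in ", path)
  }
  x
}

#' @rdname read_mappability_bed
#' @param track data frame `chrom`, `start`, `end`, `score`.
#' @export
write_mappability_bed <- function(track, path) {
  write.table(track[c("chrom", "start", "end", "score")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write gene annotations (GFF3, 1-based closed)
#'
#' Only `gene` features are read; the `ID` attribute becomes `gene_id`.
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(v) length(v) >= 9 && v[3] == "gene", logical(1))
  f <- f[keep]
  if (length(f) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0)))
  }
  data.frame(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 4)),
    end = as.numeric(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    gene_id = sub("^.*ID=([^;]+).*$", "\\1", vapply(f, `[`, "", 9))
  )
}

#' @rdname read_genes_gff3
#' @param genes data frame `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(genes$chrom, "nectarpe", "gene", genes$start, genes$end,
                   ".", genes$strand, ".",
                   sprintf("ID=%s;Name=%s", genes$gene_id, genes$gene_id),
                   sep = "\t"), con)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, master seed, package version and input-file
#' checksums so a pipeline output can be reproduced from the manifest alone.
#'
#' @param path output JSON path.
#' @param config named list of stage configurations (echoed verbatim).
#' @param seed master seed.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(0)) {
  manifest <- list(
    package = "nectarpe",
    version = as.character(utils::packageVersion("nectarpe")),
    seed = seed,
    config = config,
    inputs = if (length(inputs) > 0) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
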