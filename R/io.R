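#' Write genotypes as a minimal VCF with ancestral-allele annotation
#'
#' Emits an uncompressed VCFv4.2 with GT-only FORMAT and an `AA=` INFO tag
#' carrying the ancestral allele base (omitted when unknown). Positions
#' are converted from the package's 0-based convention to VCF's 1-based.
#' [read_vcf()] inverts the writer exactly, so write-read-write round
#' trips are byte-identical.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$individuals), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  info <- ifelse(v$ancestral == "ref", paste0("AA=", v$ref),
          ifelse(v$ancestral == "alt", paste0("AA=", v$alt), "."))
  for (i in seq_len(nrow(v))) {
    g <- geno$dosage[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(v$chrom[i], format(v$pos[i] + 1, scientific = FALSE),
                       v$id[i], v$ref[i], v$alt[i], ".", "PASS", info[i],
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Parses biallelic records with GT calls and an optional `AA=` INFO tag;
#' the ancestral allele is matched against REF/ALT (anything else, or a
#' missing tag, becomes `"unknown"`).
#'
#' @param path VCF path (uncompressed).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  inds <- header[-(1:9)]
  rec <- strsplit(body[-1L], "\t", fixed = TRUE)
  n <- length(rec)
  dosage <- matrix(NA_integer_, nrow = n, ncol = length(inds))
  v <- data.frame(id = character(n), chrom = character(n), pos = numeric(n),
                  ref = character(n), alt = character(n),
                  ancestral = character(n))
  for (i in seq_len(n)) {
    f <- rec[[i]]
    v$chrom[i] <- f[1L]
    v$pos[i] <- as.numeric(f[2L]) - 1
    v$id[i] <- f[3L]
    v$ref[i] <- f[4L]
    v$alt[i] <- f[5L]
    aa <- sub("^.*AA=([^;]*).*$", "\\1", f[8L])
    v$ancestral[i] <- if (!grepl("AA=", f[8L])) "unknown"
      else if (aa == f[4L]) "ref"
      else if (aa == f[5L]) "alt"
      else "unknown"
    gt <- sub(":.*$", "", f[-(1:9)])
    alt_count <- vapply(strsplit(gt, "[/|]"), function(al) {
      if (any(al == ".")) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
    dosage[i, ] <- alt_count
  }
  genotype_matrix(dosage, v, inds)
}

#' Read/write phenotype tables as TSV
#'
#' @param path File path.
#' @return For the reader, a data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(individual = "character"))
}

#' @rdname read_phenotypes
#' @param tab Phenotype data frame.
#' @export
write_phenotypes <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write variant consequence annotations as TSV
#'
#' Columns: `id`, `consequence`, `damaging` (logical), `ancestral`.
#'
#' @param path File path.
#' @return For the reader, a data frame.
#' @export
read_annotations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param ann Annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' @param manifest Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
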