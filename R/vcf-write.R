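## Minimal VCF 4.2 body writer for the record data frames the simulator and
## the projection step emit; output is validated by round-tripping through
## VariantAnnotation::readVcf in the test suite.

write_simple_vcf <- function(recs, path, chrom, contig_length,
                             samples = character(0), info = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"caller or embedded record\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0L) c("FORMAT", samples)),
          collapse = "\t"))
  writeLines(header, con)
  n <- nrow(recs)
  if (n == 0L) return(invisible(path))
  ids <- if (!is.null(recs$id)) recs$id else rep(".", n)
  info_col <- if (!is.null(info)) info else rep(".", n)
  for (i in seq_len(n)) {
    fields <- c(chrom, recs$pos[i], ids[i], recs$ref[i], recs$alt[i],
                ".", "PASS", info_col[i])
    if (length(samples) > 0L) {
      gts <- vapply(samples, function(s) {
        v <- recs[[paste0("gt.", s)]][i]
        if (is.na(v) || v == "") "." else v
      }, "")
      fields <- c(fields, "GT", gts)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
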