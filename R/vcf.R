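# VCF 4.2 output and a thin reader for round-tripping insertion calls.

vcf_filter_labels <- c("te_overlap", "low_te_identity",
                       "low_genome_identity", "inconsistent_breakpoint",
                       "single_end")

#' Write insertion calls as VCF 4.2
#'
#' One record per call with a symbolic mobile-element ALT
#' (\code{<INS:ME:LINE1>} or \code{<INS:ME:ALU>}). POS is the 1-based
#' position of the last reference base before the inserted sequence;
#' hallmark annotations travel in INFO, per-sample junction support in a
#' per-sample \code{AD} FORMAT field, and filter labels in FILTER.
#'
#' @param calls Data.frame from [pairAndAnnotate()]/[countSupport()].
#' @param reference Reference genome [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeInsertionVcf <- function(calls, reference, path) {
  gs <- as.character(reference)
  sup_cols <- grep("^support\\.", names(calls), value = TRUE)
  samples <- sub("^support\\.", "", sup_cols)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=retrocall",
    sprintf("##contig=<ID=%s,length=%d>", names(gs), nchar(gs)),
    "##ALT=<ID=INS:ME:LINE1,Description=\"LINE-1 mobile element insertion\">",
    "##ALT=<ID=INS:ME:ALU,Description=\"Alu mobile element insertion\">",
    "##INFO=<ID=MEFAM,Number=1,Type=String,Description=\"TE subfamily of the inserted element\">",
    "##INFO=<ID=MESTRAND,Number=1,Type=String,Description=\"Element strand\">",
    "##INFO=<ID=TSDLEN,Number=1,Type=Integer,Description=\"Target-site duplication length\">",
    "##INFO=<ID=TSDSEQ,Number=1,Type=String,Description=\"Target-site duplication sequence\">",
    "##INFO=<ID=DELLEN,Number=1,Type=Integer,Description=\"Genomic deletion at the integration site\">",
    "##INFO=<ID=POLYA,Number=1,Type=Integer,Description=\"Poly-A tail length\">",
    "##INFO=<ID=CONS,Number=2,Type=Integer,Description=\"Inserted consensus interval (1-based start,end)\">",
    "##INFO=<ID=BPL,Number=1,Type=Integer,Description=\"Left-clip junction (first aligned base after the insertion)\">",
    "##INFO=<ID=BPR,Number=1,Type=Integer,Description=\"Right-clip junction (last aligned base before the insertion)\">",
    "##INFO=<ID=SC,Number=1,Type=Float,Description=\"Strand confidence\">",
    "##INFO=<ID=FC,Number=1,Type=Float,Description=\"Family confidence\">",
    "##INFO=<ID=PC,Number=1,Type=Float,Description=\"Position confidence\">",
    "##INFO=<ID=MH,Number=1,Type=Integer,Description=\"Junction microhomology vs the reference\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", vcf_filter_labels,
            c("breakpoint inside an annotated reference TE interval",
              "cluster consensus under 90 percent identity to the TE consensus over 30 nt",
              "genomic side under 95 percent identity to the reference",
              "breakpoint not reproduced by independent realignment",
              "only one junction detected")),
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Non-duplicate junction-spanning reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  body <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    pos <- if (!is.na(calls$bp_right[i])) calls$bp_right[i] else
      calls$bp_left[i] - 1L
    refbase <- substr(gs[calls$contig[i]], pos, pos)
    alt <- if (calls$family[i] %in% "Alu") "<INS:ME:ALU>" else
      "<INS:ME:LINE1>"
    info <- paste0(
      "MEFAM=", calls$family[i],
      ";MESTRAND=", calls$strand[i],
      ";TSDLEN=", calls$tsd_len[i],
      if (nzchar(calls$tsd_seq[i])) paste0(";TSDSEQ=", calls$tsd_seq[i]) else "",
      ";DELLEN=", calls$deletion_len[i],
      ";POLYA=", calls$polya_len[i],
      ";CONS=", ifelse(is.na(calls$cons_start[i]), ".", calls$cons_start[i]),
      ",", ifelse(is.na(calls$cons_end[i]), ".", calls$cons_end[i]),
      ";BPR=", ifelse(is.na(calls$bp_right[i]), ".", calls$bp_right[i]),
      ";BPL=", ifelse(is.na(calls$bp_left[i]), ".", calls$bp_left[i]),
      ";SC=", format(calls$strand_confidence[i], digits = 4),
      ";FC=", format(calls$family_confidence[i], digits = 4),
      ";PC=", format(calls$position_confidence[i], digits = 4),
      ";MH=", calls$microhomology[i])
    filt <- if (calls$filters[i] == "") "PASS" else
      gsub(",", ";", calls$filters[i])
    fields <- c(calls$contig[i], pos, calls$call_id[i], refbase, alt, ".",
                filt, info)
    if (length(samples))
      fields <- c(fields, "AD",
                  vapply(sup_cols, function(cc) as.character(calls[[cc]][i]),
                         character(1L)))
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a retrocall insertion VCF back into a call table
#'
#' @param path VCF file written by [writeInsertionVcf()].
#' @return Data.frame with the call columns encoded in the VCF.
#' @export
readInsertionVcf <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character()
  out <- list()
  for (b in body) {
    f <- strsplit(b, "\t")[[1L]]
    info <- strsplit(f[8L], ";")[[1L]]
    kv <- strsplit(info, "=")
    vals <- stats::setNames(vapply(kv, function(x) x[2L], character(1L)),
                            vapply(kv, function(x) x[1L], character(1L)))
    geti <- function(k) {
      v <- vals[[k]] %||% NA_character_
      if (is.na(v) || v == ".") NA_integer_ else as.integer(v)
    }
    getn <- function(k) as.numeric(vals[[k]] %||% NA_character_)
    cons <- strsplit(vals[["CONS"]] %||% ".,.", ",")[[1L]]
    row <- data.frame(
      contig = f[1L], pos = as.integer(f[2L]), call_id = f[3L],
      family = vals[["MEFAM"]], strand = vals[["MESTRAND"]],
      tsd_len = geti("TSDLEN"),
      tsd_seq = vals[["TSDSEQ"]] %||% "",
      deletion_len = geti("DELLEN"), polya_len = geti("POLYA"),
      cons_start = if (cons[1L] == ".") NA_integer_ else as.integer(cons[1L]),
      cons_end = if (cons[2L] == ".") NA_integer_ else as.integer(cons[2L]),
      bp_right = geti("BPR"), bp_left = geti("BPL"),
      strand_confidence = getn("SC"), family_confidence = getn("FC"),
      position_confidence = getn("PC"), microhomology = geti("MH"),
      filters = if (f[7L] %in% c("PASS", ".")) "" else
        gsub(";", ",", f[7L]),
      stringsAsFactors = FALSE)
    if (length(samples)) {
      for (si in seq_along(samples))
        row[[paste0("support.", samples[si])]] <- as.integer(f[9L + si])
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
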