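#' Construct an SvCallSet
#'
#' @param sampleId sample identifier.
#' @param records `data.frame` with columns `svType`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `precise`, `filterPass`, `readSupport`, `mateId`
#'   (missing optional columns are filled with defaults).
#' @return an [SvCallSet-class].
#' @export
svCallSet <- function(sampleId, records) {
  if (is.null(records$mateId)) records$mateId <- NA_character_
  if (is.null(records$readSupport)) records$readSupport <- NA_integer_
  if (is.null(records$precise)) records$precise <- TRUE
  if (is.null(records$filterPass)) records$filterPass <- TRUE
  records <- records[, .svRecordCols]
  rownames(records) <- NULL
  new("SvCallSet", sampleId = sampleId, records = records)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "SvCallSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("svRecords", "SvCallSet", function(x) x@records)

setMethod("show", "SvCallSet", function(object) {
  rec <- object@records
  cat(sprintf("SvCallSet '%s': %d record(s)\n", object@sampleId, nrow(rec)))
  if (nrow(rec)) {
    print(table(rec$svType))
  }
})

## Parse a VCF BND ALT such as A[chr2:12345[ or ]chr2:12345]A.
.parseBndAlt <- function(alt) {
  m <- regmatches(alt, regexec("[][]([^:]+):([0-9]+)[][]", alt))[[1L]]
  if (length(m) == 3L) {
    list(chrom2 = m[2L], pos2 = as.numeric(m[3L]))
  } else {
    NULL
  }
}

.infoField <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

.infoFlag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|$)"), info)
}

#' Read a Delly-dialect structural-variant VCF
#'
#' Parses a VCF 4.x with Delly-style INFO fields (`SVTYPE`, `CHR2`, `END`,
#' `PE`, `SR`, `PRECISE`/`IMPRECISE`, `MATEID`). Only records flagged both
#' `PASS` and `PRECISE` are retained (the number dropped is logged); records
#' without an `SVTYPE` are skipped with a warning. BND mate coordinates are
#' taken from the bracketed ALT, falling back to `CHR2`/`END`.
#'
#' @param path VCF file path.
#' @param sampleId sample identifier (defaults to the file base name).
#' @param keepAll keep non-PASS / imprecise records too (flags are retained
#'   either way; downstream statistics only ever use passing records).
#' @return an [SvCallSet-class] with 1-based positions.
#' @export
readSvVcf <- function(path, sampleId = NULL, keepAll = FALSE) {
  if (!file.exists(path)) {
    stop("cannot read VCF: ", path)
  }
  sampleId <- sampleId %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    return(svCallSet(sampleId, data.frame(
      svType = character(0), chrom1 = character(0), pos1 = numeric(0),
      chrom2 = character(0), pos2 = numeric(0), precise = logical(0),
      filterPass = logical(0), readSupport = integer(0),
      mateId = character(0), stringsAsFactors = FALSE)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(fix))
  nNoType <- 0L
  for (i in seq_len(nrow(fix))) {
    info <- fix$INFO[i]
    svType <- .infoField(info, "SVTYPE")
    if (is.na(svType)) {
      nNoType <- nNoType + 1L
      next
    }
    chrom1 <- fix$CHROM[i]
    pos1 <- as.numeric(fix$POS[i])
    chrom2 <- chrom1
    pos2 <- pos1
    if (svType == "BND") {
      bnd <- .parseBndAlt(fix$ALT[i])
      if (!is.null(bnd)) {
        chrom2 <- bnd$chrom2
        pos2 <- bnd$pos2
      } else {
        c2 <- .infoField(info, "CHR2")
        chrom2 <- if (is.na(c2)) chrom1 else c2
        pos2 <- as.numeric(.infoField(info, "END"))
      }
    } else {
      endv <- .infoField(info, "END")
      if (!is.na(endv)) pos2 <- as.numeric(endv)
      c2 <- .infoField(info, "CHR2")
      if (!is.na(c2)) chrom2 <- c2
    }
    pe <- suppressWarnings(as.integer(.infoField(info, "PE")))
    rows[[i]] <- data.frame(
      svType = svType, chrom1 = chrom1, pos1 = pos1,
      chrom2 = chrom2, pos2 = pos2,
      precise = .infoFlag(info, "PRECISE"),
      filterPass = identical(fix$FILTER[i], "PASS"),
      readSupport = pe, mateId = .infoField(info, "MATEID"),
      stringsAsFactors = FALSE)
  }
  if (nNoType) {
    warning(nNoType, " record(s) without SVTYPE skipped in ", path)
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rec)) {
    rec <- data.frame(svType = character(0), chrom1 = character(0),
                      pos1 = numeric(0), chrom2 = character(0),
                      pos2 = numeric(0), precise = logical(0),
                      filterPass = logical(0), readSupport = integer(0),
                      mateId = character(0), stringsAsFactors = FALSE)
  }
  if (!keepAll) {
    keep <- rec$filterPass & rec$precise
    nDropped <- sum(!keep)
    if (nDropped) {
      .mmLog("readSvVcf(%s): dropped %d non-PASS/imprecise record(s), kept %d",
             sampleId, nDropped, sum(keep))
    }
    rec <- rec[keep, , drop = FALSE]
  }
  svCallSet(sampleId, rec)
}

#' Write an SvCallSet as a Delly-dialect VCF 4.2
#'
#' @param callSet an [SvCallSet-class].
#' @param genome a [GenomeBuild-class] for the contig header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSvVcf <- function(callSet, genome, path) {
  rec <- svRecords(callSet)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%.0f>", chromNames(genome),
            unname(chromLengths(genome))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome for second coordinate\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the structural variant\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split-read support\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise structural variant\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##FILTER=<ID=LowQual,Description=\"Low quality call\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (nrow(rec)) {
    for (i in seq_len(nrow(rec))) {
      r <- rec[i, ]
      id <- sprintf("%s%05d", r$svType, i)
      prec <- if (isTRUE(r$precise)) "PRECISE" else "IMPRECISE"
      pe <- if (is.na(r$readSupport)) 4L else r$readSupport
      filt <- if (isTRUE(r$filterPass)) "PASS" else "LowQual"
      if (r$svType == "BND") {
        mate <- sprintf("%s%05dM", r$svType, i)
        infoA <- sprintf("%s;SVTYPE=BND;CHR2=%s;END=%.0f;PE=%d;SR=%d;MATEID=%s",
                         prec, r$chrom2, r$pos2, pe, pe, mate)
        infoB <- sprintf("%s;SVTYPE=BND;CHR2=%s;END=%.0f;PE=%d;SR=%d;MATEID=%s",
                         prec, r$chrom1, r$pos1, pe, pe, id)
        lines <- c(lines,
          sprintf("%s\t%.0f\t%s\tN\tN[%s:%.0f[\t.\t%s\t%s",
                  r$chrom1, r$pos1, id, r$chrom2, r$pos2, filt, infoA),
          sprintf("%s\t%.0f\t%s\tN\t]%s:%.0f]N\t.\t%s\t%s",
                  r$chrom2, r$pos2, mate, r$chrom1, r$pos1, filt, infoB))
      } else {
        alt <- sprintf("<%s>", r$svType)
        info <- sprintf("%s;SVTYPE=%s;CHR2=%s;END=%.0f;PE=%d;SR=%d",
                        prec, r$svType, r$chrom2, r$pos2, pe, pe)
        lines <- c(lines,
          sprintf("%s\t%.0f\t%s\tN\t%s\t.\t%s\t%s",
                  r$chrom1, r$pos1, id, alt, filt, info))
      }
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
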