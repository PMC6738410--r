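## Readers and writers for the plain-text formats the toolkit exchanges:
## beta matrices, clock coefficient tables, probe manifests (TSV or BED)
## and sample annotation tables.  All writers prepend a '#' comment line
## carrying the toolkit version; readers skip '#' lines.

.versionHeader <- function(what) {
    sprintf("# MethylTL %s %s",
            as.character(utils::packageVersion("MethylTL")), what)
}

.readTable <- function(path, sep = "\t", header = TRUE, ...) {
    utils::read.delim(path, sep = sep, header = header, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE, ...)
}

#' Read a beta matrix from delimited text
#'
#' Expects probe ids in the first column and sample ids in the header
#' (Illumina probes-by-samples orientation).  A transposed file can be read
#' by setting \code{orientation = "samples_by_probes"}.  Cells that are
#' empty or \code{NA} are kept as missing values; they are recorded in the
#' missing mask and never imputed here.
#'
#' @param path file path; tab-separated unless \code{sep} says otherwise.
#' @param orientation \code{"probes_by_samples"} (default) or
#'   \code{"samples_by_probes"}.
#' @param sep field separator.
#' @return a \linkS4class{BetaMatrix}; values outside \[0, 1\] or duplicate
#'   ids raise a validation error naming the offender.
#' @export
readBetaMatrix <- function(path,
                           orientation = c("probes_by_samples",
                                           "samples_by_probes"),
                           sep = "\t") {
    orientation <- match.arg(orientation)
    df <- .readTable(path, sep = sep)
    if (ncol(df) < 2L)
        stop("beta matrix file needs an id column plus at least one sample")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (orientation == "samples_by_probes") m <- t(m)
    BetaMatrix(m)
}

#' Write a beta matrix to tab-separated text
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(x, path) {
    stopifnot(is(x, "BetaMatrix"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.versionHeader("beta matrix (probes x samples)"), con)
    df <- data.frame(probe_id = probeIds(x), betaValues(x),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a clock coefficient table
#'
#' The format is two tab-separated columns, \code{probe_id} and
#' \code{weight}, with exactly one intercept record under the reserved id
#' \code{"(Intercept)"}.  Training metadata written by
#' \code{\link{writeClockCoefficients}} (alpha, lambda, selection rule) is
#' recovered from header comments when present.
#'
#' @param path file path.
#' @return a \linkS4class{ClockModel}.
#' @export
readClockCoefficients <- function(path) {
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "#")]
    getMeta <- function(key, default) {
        hit <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
        if (!length(hit)) return(default)
        sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1L])
    }
    df <- .readTable(path)
    if (!all(c("probe_id", "weight") %in% names(df)))
        stop("coefficient file must have columns 'probe_id' and 'weight'")
    isInt <- df$probe_id == "(Intercept)"
    if (sum(isInt) != 1L)
        stop("coefficient file must contain exactly one '(Intercept)' record")
    probes <- df$probe_id[!isInt]
    dup <- probes[duplicated(probes)]
    if (length(dup))
        stop("duplicate probe id(s) in coefficient file: ",
             paste(unique(dup), collapse = ", "))
    ClockModel(intercept = df$weight[isInt],
               weights = setNames(df$weight[!isInt], probes),
               alpha = as.numeric(getMeta("alpha", NA_real_)),
               lambda = as.numeric(getMeta("lambda", NA_real_)),
               lambdaRule = getMeta("lambda_rule", "fixed"))
}

#' Write a clock coefficient table
#'
#' @param model a \linkS4class{ClockModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeClockCoefficients <- function(model, path) {
    stopifnot(is(model, "ClockModel"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(.versionHeader("clock coefficients (kb per unit beta)"),
                 sprintf("# alpha: %.17g", model@alpha),
                 sprintf("# lambda: %.17g", model@lambda),
                 sprintf("# lambda_rule: %s", model@lambdaRule)), con)
    df <- data.frame(
        probe_id = c("(Intercept)", names(model@weights)),
        weight = c(model@intercept, unname(model@weights)))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' hg19 chromosome lengths
#'
#' Lengths (bp) of chr1-chr22, chrX and chrY in the hg19 assembly, the
#' 450K-era default used when a manifest does not supply its own lengths.
#'
#' @return a named integer vector of chromosome lengths.
#' @export
hg19ChromLengths <- function() {
    path <- system.file("extdata", "hg19_chrom_lengths.tsv",
                        package = "MethylTL", mustWork = TRUE)
    df <- .readTable(path)
    setNames(as.integer(df$length), df$chrom)
}

#' Read a probe manifest with genomic coordinates
#'
#' Internal coordinates are 1-based and fully closed.  The BED dialect
#' (0-based, half-open) is converted on read: a BED interval
#' \code{[start, end)} maps to 1-based position \code{start + 1}.
#'
#' @param path file path.
#' @param dialect \code{"tsv_1based"} (columns \code{probe_id},
#'   \code{chrom}, \code{pos}) or \code{"bed"} (BED4:
#'   chrom, start, end, name).
#' @param chromLengths named vector of chromosome lengths; defaults to the
#'   bundled hg19 table.
#' @return a \link[GenomicRanges]{GRanges} of width-1 positions named by
#'   probe id, with \code{seqlengths} set.
#' @export
readManifest <- function(path, dialect = c("tsv_1based", "bed"),
                         chromLengths = hg19ChromLengths()) {
    dialect <- match.arg(dialect)
    if (dialect == "tsv_1based") {
        df <- .readTable(path)
        if (!all(c("probe_id", "chrom", "pos") %in% names(df)))
            stop("tsv_1based manifest needs columns probe_id, chrom, pos")
        probe <- as.character(df$probe_id)
        chrom <- as.character(df$chrom)
        pos <- as.integer(df$pos)
    } else {
        df <- .readTable(path, header = FALSE)
        if (ncol(df) < 4L)
            stop("BED manifest needs 4 columns: chrom, start, end, name")
        probe <- as.character(df[[4L]])
        chrom <- as.character(df[[1L]])
        pos <- as.integer(df[[2L]]) + 1L
    }
    if (anyDuplicated(probe))
        stop("duplicate probe id(s) in manifest: ",
             paste(unique(probe[duplicated(probe)]), collapse = ", "))
    unknown <- setdiff(unique(chrom), names(chromLengths))
    if (length(unknown))
        stop("chromosome(s) without known length: ",
             paste(unknown, collapse = ", "),
             "; supply chromLengths")
    if (any(pos < 1L))
        stop("position < 1 at probe(s): ",
             paste(probe[pos < 1L], collapse = ", "))
    tooFar <- pos > chromLengths[chrom]
    if (any(tooFar))
        stop("position exceeds chromosome length at probe(s): ",
             paste(probe[tooFar], collapse = ", "))
    lv <- intersect(names(chromLengths), unique(chrom))
    gr <- GenomicRanges::GRanges(
        seqnames = factor(chrom, levels = lv),
        ranges = IRanges::IRanges(start = pos, width = 1L))
    names(gr) <- probe
    GenomeInfoDb::seqlengths(gr) <- chromLengths[lv]
    gr
}

#' Write a probe manifest
#'
#' @param gr a width-1 \link[GenomicRanges]{GRanges} named by probe id.
#' @param path output file.
#' @param dialect \code{"tsv_1based"} or \code{"bed"} (converted to
#'   0-based half-open on write, so BED round-trips are identity).
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(gr, path, dialect = c("tsv_1based", "bed")) {
    dialect <- match.arg(dialect)
    stopifnot(is(gr, "GRanges"), !is.null(names(gr)))
    if (dialect == "tsv_1based") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(.versionHeader("probe manifest (1-based)"), con)
        df <- data.frame(probe_id = names(gr),
                         chrom = as.character(GenomicRanges::seqnames(gr)),
                         pos = GenomicRanges::start(gr))
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::start(gr),
                         names(gr))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

.sampleNumeric <- c("age", "pack_years", "bmi", "ltl_kb", "time")

#' Read a sample annotation table
#'
#' Tab-separated with a \code{sample_id} column; recognised covariates are
#' \code{cohort_id}, \code{age} (years), \code{sex} (female/male),
#' \code{ethnicity}, \code{batch}, \code{pack_years}, \code{ever_smoker},
#' \code{bmi} (kg/m^2), \code{ltl_kb} (measured telomere length, kb),
#' \code{time} (follow-up, years) and \code{event} (0/1).  Basic sanity
#' constraints (nonnegative age, time, pack-years) are enforced.
#'
#' @param path file path.
#' @return a \code{data.frame}.
#' @export
readSampleTable <- function(path) {
    df <- .readTable(path)
    if (!"sample_id" %in% names(df))
        stop("sample table needs a 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id(s)")
    for (col in c("age", "time", "pack_years")) {
        if (col %in% names(df) && any(df[[col]] < 0, na.rm = TRUE))
            stop("negative values in column '", col, "'")
    }
    if ("ever_smoker" %in% names(df))
        df$ever_smoker <- as.logical(df$ever_smoker)
    if ("event" %in% names(df))
        df$event <- as.integer(df$event)
    df
}

#' Write a sample annotation table
#'
#' @param df a \code{data.frame} with a \code{sample_id} column.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(df, path) {
    stopifnot("sample_id" %in% names(df))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.versionHeader("sample table"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
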