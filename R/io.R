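#' Read a phase-format haplotype file with a genetic map
#'
#' Reads ChromoPainter-style phase format: a haplotype count line, a SNP
#' count line, a positions line prefixed \code{"P"}, then one 0/1 string per
#' haplotype.  Genetic positions are obtained by linear interpolation of the
#' map file's anchor points (flat beyond the ends).
#'
#' @param path phase file.
#' @param map_path genetic map file: whitespace-separated columns
#'   \code{bp cM} or \code{bp rate cM} (the rate column is ignored); a
#'   non-numeric header line is skipped.
#' @param chrom chromosome name to record.
#' @param pop_path optional two-column file (sample id, population) used to
#'   attach population labels.
#' @return list with elements \code{panel} (\linkS4class{HaplotypePanel}) and
#'   \code{map} (\linkS4class{GeneticMap}).
#' @export
readPhase <- function(path, map_path, chrom = "1", pop_path = NULL) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    nh <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]][1])
    ns <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]][1])
    ptoks <- strsplit(trimws(ln[3]), "\\s+")[[1]]
    if (ptoks[1] != "P") stop("positions line must be prefixed 'P'")
    pos <- as.integer(ptoks[-1])
    if (length(pos) != ns) stop("position count disagrees with SNP count")
    if (any(diff(pos) <= 0)) stop("positions must be strictly ascending")
    hapstr <- ln[3 + seq_len(nh)]
    if (any(is.na(hapstr)) || length(hapstr) < nh)
        stop("fewer haplotype rows than declared")
    if (any(nchar(hapstr) != ns)) stop("haplotype rows must have one allele per SNP")
    if (any(grepl("[^01]", hapstr))) stop("haplotype rows must be 0/1 strings")
    A <- matrix(0L, nh, ns)
    for (i in seq_len(nh))
        A[i, ] <- as.integer(charToRaw(hapstr[i])) - 48L
    if (nh %% 2 != 0) stop("haplotype count must be even")
    ids <- sprintf("ind%d", seq_len(nh / 2))
    pops <- character(0)
    if (!is.null(pop_path)) {
        lab <- readPopLabels(pop_path)
        pops <- unname(lab[ids])
        if (anyNA(pops)) stop("population labels missing for some samples")
    }
    panel <- new("HaplotypePanel", chrom = chrom, positions = pos,
                 alleles = A, sampleIds = ids, popLabels = pops)
    map <- readGeneticMap(map_path, pos, chrom = chrom)
    list(panel = panel, map = map)
}

#' Write a panel in phase format
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePhase <- function(panel, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(as.character(nHaps(panel)), as.character(nSNPs(panel)),
                 paste("P", paste(positions(panel), collapse = " "))), con)
    A <- alleles(panel)
    writeLines(vapply(seq_len(nrow(A)),
                      function(i) paste(A[i, ], collapse = ""), ""), con)
    invisible(path)
}

#' Interpolate a genetic map onto SNP positions
#'
#' @param map_path map file (see \code{\link{readPhase}}), or a two-column
#'   data.frame of anchors (bp, cM).
#' @param positions integer bp positions to interpolate at.
#' @param chrom chromosome name.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(map_path, positions, chrom = "1") {
    if (is.data.frame(map_path)) {
        anchors <- map_path
    } else {
        ln <- readLines(map_path)
        ln <- ln[nzchar(trimws(ln))]
        first <- strsplit(trimws(ln[1]), "\\s+")[[1]]
        if (suppressWarnings(anyNA(as.numeric(first)))) ln <- ln[-1]
        toks <- strsplit(trimws(ln), "\\s+")
        ncols <- lengths(toks)
        if (!all(ncols == ncols[1]) || !ncols[1] %in% 2:3)
            stop("map must have 2 (bp, cM) or 3 (bp, rate, cM) columns")
        num <- matrix(as.numeric(unlist(toks)), ncol = ncols[1], byrow = TRUE)
        anchors <- data.frame(bp = num[, 1], cm = num[, ncols[1]])
    }
    if (!nrow(anchors)) stop("empty genetic map")
    anchors <- anchors[order(anchors$bp), , drop = FALSE]
    if (nrow(anchors) == 1) {
        cm <- rep(anchors$cm[1], length(positions))
    } else {
        cm <- approx(anchors$bp, anchors$cm, xout = positions,
                     rule = 2, ties = "ordered")$y
    }
    new("GeneticMap", chrom = chrom, positions = as.integer(positions),
        cm = cm, chromLengthCM = max(cm, anchors$cm))
}

#' Read population labels
#'
#' @param path two-column whitespace-separated file: sample id, population.
#' @return named character vector (names = sample ids).
#' @export
readPopLabels <- function(path) {
    tb <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tb) < 2) stop("label file must have two columns")
    setNames(as.character(tb[[2]]), as.character(tb[[1]]))
}

#' Read phased haplotypes from a VCF file
#'
#' Only biallelic SNP records with fully phased \code{"|"}-separated GT
#' fields are used.  In strict mode (default) a missing or unphased genotype
#' is an error; in lenient mode the offending record is skipped.
#'
#' @param path VCF file (may be gzipped).
#' @param map_path genetic map file or anchor data.frame (see
#'   \code{\link{readGeneticMap}}).
#' @param strict logical, see above.
#' @param pop_path optional population-label file.
#' @return list with \code{panel} and \code{map} as in \code{\link{readPhase}}.
#' @export
readVCF <- function(path, map_path, strict = TRUE, pop_path = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- v@gt[, -1, drop = FALSE]
    samples <- colnames(gt)
    gtfield <- sub(":.*$", "", gt)
    ok <- grepl("^[01]\\|[01]$", gtfield[, 1])
    for (j in seq_len(ncol(gtfield))[-1])
        ok <- ok & grepl("^[01]\\|[01]$", gtfield[, j])
    biall <- !grepl(",", fix[, "ALT"]) &
        nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
    if (strict && any(!ok))
        stop("missing or unphased genotypes in strict mode (e.g. record ",
             which(!ok)[1], ")")
    keep <- ok & biall
    if (!any(keep)) stop("no usable biallelic phased records")
    gtfield <- gtfield[keep, , drop = FALSE]
    pos <- as.integer(fix[keep, "POS"])
    if (any(diff(pos) <= 0)) stop("positions must be strictly ascending")
    chrom <- unique(fix[keep, "CHROM"])
    if (length(chrom) != 1) stop("expected a single chromosome")
    K <- nrow(gtfield); n <- length(samples)
    A <- matrix(0L, 2L * n, K)
    for (j in seq_len(n)) {
        A[2L * j - 1L, ] <- as.integer(substr(gtfield[, j], 1L, 1L))
        A[2L * j, ]      <- as.integer(substr(gtfield[, j], 3L, 3L))
    }
    pops <- character(0)
    if (!is.null(pop_path)) {
        lab <- readPopLabels(pop_path)
        pops <- unname(lab[samples])
        if (anyNA(pops)) stop("population labels missing for some samples")
    }
    panel <- new("HaplotypePanel", chrom = chrom, positions = pos,
                 alleles = A, sampleIds = samples, popLabels = pops)
    list(panel = panel, map = readGeneticMap(map_path, pos, chrom = chrom))
}

.openOut <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Write a per-SNP painting probability track
#'
#' Tab-separated, one row per SNP, header row with population names,
#' probabilities at fixed precision.  Rows must sum to 1 (checked to 1e-6
#' before rounding).
#'
#' @param probs K x npop matrix (SNPs in rows) with column names, e.g.
#'   \code{t(popProbs(res)[[h]])}.
#' @param path output file; gzip-compressed when it ends in \code{.gz}.
#' @param digits decimal places (default 4).
#' @return \code{path}, invisibly.
#' @export
writePainting <- function(probs, path, digits = 4) {
    rs <- rowSums(probs)
    if (any(abs(rs - 1) > 1e-6))
        stop("painting rows must sum to 1 (max deviation ",
             signif(max(abs(rs - 1)), 3), ")")
    con <- .openOut(path)
    on.exit(close(con))
    cn <- colnames(probs)
    if (is.null(cn)) cn <- sprintf("pop%d", seq_len(ncol(probs)))
    writeLines(paste(cn, collapse = "\t"), con)
    fmt <- paste0("%.", digits, "f")
    body <- apply(probs, 1, function(r) paste(sprintf(fmt, r), collapse = "\t"))
    writeLines(body, con)
    invisible(path)
}

#' Read back a painting track written by \code{writePainting}
#'
#' @param path file written by \code{\link{writePainting}}.
#' @return numeric matrix with the header row as column names.
#' @export
readPainting <- function(path) {
    tb <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    as.matrix(tb)
}

#' Write a chunk summary table
#'
#' @param summary matrix of chunk lengths or counts (rows = recipients,
#'   columns = donors or donor populations) with dimnames.
#' @param path output file; gzip-compressed when it ends in \code{.gz}.
#' @param digits decimal places (default 6).
#' @return \code{path}, invisibly.
#' @export
writeChunks <- function(summary, path, digits = 6) {
    con <- .openOut(path)
    on.exit(close(con))
    cn <- colnames(summary)
    if (is.null(cn)) cn <- sprintf("donor%d", seq_len(ncol(summary)))
    writeLines(paste(c("recipient", cn), collapse = "\t"), con)
    rn <- rownames(summary)
    if (is.null(rn)) rn <- sprintf("target%d", seq_len(nrow(summary)))
    fmt <- paste0("%.", digits, "f")
    writeLines(vapply(seq_len(nrow(summary)), function(i)
        paste(c(rn[i], sprintf(fmt, summary[i, ])), collapse = "\t"), ""), con)
    invisible(path)
}
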