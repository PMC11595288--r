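#' @importFrom stats cor kmeans sd rnorm runif setNames dist
#' @importFrom utils read.delim write.table combn head
NULL

LINEAGES <- c("E", "Mo", "G", "Mk")
STAGES <- c("T1", "T2", "T3")

#' Parse sample header codes into lineage/stage/replicate keys
#'
#' Sample columns are labelled `<lineage>_<stage>[_<replicate>]` with lineage
#' in E (erythroid), Mo (monocytic), G (granulocytic), Mk (megakaryocytic) and
#' stage in T1, T2, T3 (culture days 5, 10, 15). Any other code is rejected.
#'
#' @param codes character vector of sample codes.
#' @return data.frame with columns `code`, `lineage`, `stage`, `replicate`
#'   (NA when the code carries no replicate suffix).
#' @export
parse_sample_keys <- function(codes) {
  if (anyDuplicated(codes)) {
    stop("duplicate sample codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  parts <- strsplit(codes, "_", fixed = TRUE)
  parse1 <- function(code, p) {
    if (length(p) < 2L || length(p) > 3L) {
      stop("malformed sample code '", code,
           "': expected <lineage>_<stage>[_<replicate>]")
    }
    if (!p[1] %in% LINEAGES) {
      stop("unknown lineage code '", p[1], "' in sample '", code, "'")
    }
    if (!p[2] %in% STAGES) {
      stop("unknown stage code '", p[2], "' in sample '", code, "'")
    }
    rep <- NA_integer_
    if (length(p) == 3L) {
      rep <- suppressWarnings(as.integer(p[3]))
      if (is.na(rep) || rep < 1L) {
        stop("invalid replicate '", p[3], "' in sample '", code, "'")
      }
    }
    list(lineage = p[1], stage = p[2], replicate = rep)
  }
  parsed <- Map(parse1, codes, parts)
  data.frame(
    code = codes,
    lineage = vapply(parsed, `[[`, "", "lineage"),
    stage = vapply(parsed, `[[`, "", "stage"),
    replicate = vapply(parsed, `[[`, NA_integer_, "replicate"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Construct an abundance table
#'
#' Features x samples matrix of non-negative measurements (normalized
#' microarray intensity for miRNAs, pg/mL for cytokines). Missing values are
#' carried as NA and treated as masked throughout the pipeline.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample
#'   codes parseable by [parse_sample_keys()].
#' @param space `"miRNA"` or `"cytokine"`.
#' @return object of class `hn_abundance`.
#' @export
abundance_table <- function(values, space = c("miRNA", "cytokine")) {
  space <- match.arg(space)
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            nrow(values) == 0 || !is.null(rownames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative abundance at feature '", rownames(values)[neg[1, 1]],
         "', sample '", colnames(values)[neg[1, 2]], "'")
  }
  structure(
    list(values = values, samples = parse_sample_keys(colnames(values)),
         space = space),
    class = "hn_abundance"
  )
}

#' Construct a log-scale table
#'
#' Same axes as an abundance table but with signed log2 values: either log2
#' fold change against the CD34+ reference, or log2-transformed concentration.
#'
#' @param values numeric matrix (NA = masked).
#' @param space `"miRNA"` or `"cytokine"`.
#' @param transform `"logFC_vs_reference"` or `"log2_concentration"`.
#' @return object of class `hn_logfc`.
#' @export
logfc_table <- function(values, space = c("miRNA", "cytokine"),
                        transform = c("logFC_vs_reference", "log2_concentration")) {
  space <- match.arg(space)
  transform <- match.arg(transform)
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            nrow(values) == 0 || !is.null(rownames(values)))
  structure(
    list(values = values, samples = parse_sample_keys(colnames(values)),
         space = space, transform = transform),
    class = "hn_logfc"
  )
}

#' Construct a CD34+ reference profile
#'
#' @param values named non-negative numeric vector of baseline abundances.
#' @param space `"miRNA"` or `"cytokine"`.
#' @return object of class `hn_reference`.
#' @export
reference_profile <- function(values, space = c("miRNA", "cytokine")) {
  space <- match.arg(space)
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) stop("duplicate feature ids in reference")
  if (any(!is.na(values) & values < 0)) stop("negative reference value")
  structure(list(values = values, space = space), class = "hn_reference")
}

#' @export
print.hn_abundance <- function(x, ...) {
  cat(sprintf("<abundance_table> %s space: %d features x %d samples\n",
              x$space, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.hn_logfc <- function(x, ...) {
  cat(sprintf("<logfc_table> %s space (%s): %d features x %d samples\n",
              x$space, x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.hn_reference <- function(x, ...) {
  cat(sprintf("<reference_profile> %s space: %d features\n",
              x$space, length(x$values)))
  invisible(x)
}

#' Read an abundance table from delimited text
#'
#' First column holds feature ids; remaining column headers encode
#' `<lineage>_<stage>[_<replicate>]` sample keys. Missing cells are the
#' literal string `NA`.
#'
#' @param path file path (TSV by default).
#' @param space `"miRNA"` or `"cytokine"`.
#' @param sep field separator, `"\t"` or `","`.
#' @return an `hn_abundance`.
#' @export
read_abundance_table <- function(path, space = c("miRNA", "cytokine"), sep = "\t") {
  space <- match.arg(space)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a feature-id column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) == 0) storage.mode(m) <- "double"
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  abundance_table(m, space = space)
}

#' Read a log-scale table from delimited text
#'
#' @param path file path.
#' @param space `"miRNA"` or `"cytokine"`.
#' @param transform transform tag recorded on the result.
#' @param sep field separator.
#' @return an `hn_logfc`.
#' @export
read_logfc_table <- function(path, space = c("miRNA", "cytokine"),
                             transform = c("logFC_vs_reference", "log2_concentration"),
                             sep = "\t") {
  space <- match.arg(space)
  transform <- match.arg(transform)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) == 0) storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  logfc_table(m, space = space, transform = transform)
}

#' Read a CD34+ baseline profile from a 2-column table
#'
#' @param path file path to a two-column (feature id, value) delimited file.
#' @param space `"miRNA"` or `"cytokine"`.
#' @param sep field separator.
#' @return an `hn_reference`.
#' @export
read_reference_profile <- function(path, space = c("miRNA", "cytokine"), sep = "\t") {
  space <- match.arg(space)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("reference profile must have exactly 2 columns")
  reference_profile(setNames(as.numeric(df[[2]]), as.character(df[[1]])),
                    space = space)
}

#' Write a table (abundance, log-scale or reference) to delimited text
#'
#' Values are formatted with 6 significant digits so that a fixed input always
#' produces byte-identical output; masked cells are written as `NA`.
#'
#' @param table an `hn_abundance`, `hn_logfc` or `hn_reference`.
#' @param path destination file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, sep = "\t") {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 6))
  if (inherits(table, "hn_reference")) {
    df <- data.frame(feature_id = names(table$values),
                     value = fmt(table$values),
                     stringsAsFactors = FALSE)
  } else if (inherits(table, c("hn_abundance", "hn_logfc"))) {
    chr <- apply(table$values, 2, fmt)
    if (nrow(table$values) == 1L) chr <- matrix(chr, nrow = 1L,
                                                dimnames = dimnames(table$values))
    if (nrow(table$values) == 0L) {
      chr <- matrix(character(0), nrow = 0, ncol = ncol(table$values),
                    dimnames = dimnames(table$values))
    }
    ids <- rownames(table$values)
    if (is.null(ids)) ids <- character(0)
    df <- data.frame(feature_id = ids, chr,
                     stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    stop("unsupported table class: ", paste(class(table), collapse = "/"))
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# internal: samples belonging to one lineage, ordered by stage then replicate
lineage_columns <- function(table, lineage) {
  s <- table$samples
  idx <- which(s$lineage == lineage)
  idx[order(match(s$stage[idx], STAGES), s$replicate[idx], na.last = FALSE)]
}
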