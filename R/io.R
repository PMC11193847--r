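# Table dialect readers and writers. All files are UTF-8 (BA nomenclature
# uses Greek letters); lines starting with '#' are provenance headers and
# are skipped on read. Missing values use the token "NA".

.read_lines_utf8 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!startsWith(lines, "#")]
}

# strict delimited reader: every row must have exactly the header's field
# count; violations are reported with their (1-based, post-header) lines
.read_strict <- function(path, sep, required) {
  lines <- .read_lines_utf8(path)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncol <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != ncol)
  if (length(bad)) {
    stop("malformed row(s) in ", path, " at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  header <- fields[[1]]
  if (!is.null(required)) {
    miss <- setdiff(required, header)
    if (length(miss)) stop("missing column(s) in ", path, ": ",
                           paste(miss, collapse = ", "))
    if (length(header) > length(required)) {
      extra <- setdiff(header, required)
      message("ignoring extra column(s) in ", path, ": ",
              paste(extra, collapse = ", "))
    }
  }
  body <- fields[-1]
  d <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(d) <- header
  d[d == "NA"] <- NA
  d
}

# provenance header written at the top of every output file
.provenance <- function(seed = NULL, extra = NULL) {
  c(paste0("# rumenba ",
           as.character(utils::packageVersion("rumenba"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(extra)) paste0("# ", extra))
}

.write_table <- function(d, path, sep, seed = NULL, force = FALSE,
                         ascii = FALSE) {
  if (file.exists(path) && !force) {
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  }
  if (ascii) {
    for (j in seq_along(d)) {
      if (is.character(d[[j]])) d[[j]] <- ba_name_ascii(d[[j]])
    }
    names(d) <- ba_name_ascii(names(d))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  writeLines(paste(names(d), collapse = sep), con)
  if (nrow(d)) {
    body <- do.call(paste, c(lapply(d, function(x) {
      x <- as.character(x); x[is.na(x)] <- "NA"; x
    }), sep = sep))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a MAG catalog TSV
#'
#' Expected columns: mag_id, completeness, contamination, taxonomy
#' (semicolon-delimited GTDB-style ranks).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_mag_catalog <- function(path) {
  d <- .read_strict(path, "\t",
                    c("mag_id", "completeness", "contamination", "taxonomy"))
  d$completeness <- as.numeric(d$completeness)
  d$contamination <- as.numeric(d$contamination)
  d
}

#' Read a gene-to-KO annotation TSV
#'
#' Expected columns: gene_id, mag_id, ko_id (KofamScan-style significant
#' hits; a score column, if present, is ignored with a note).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ko_table <- function(path) {
  .read_strict(path, "\t", c("gene_id", "mag_id", "ko_id"))
}

#' Read an isolate-organism annotation TSV (organism_id, ko_id)
#' @param path file path.
#' @return data.frame.
#' @export
read_isolate_table <- function(path) {
  .read_strict(path, "\t", c("organism_id", "ko_id"))
}

#' Read a GTDB to NCBI species-name map TSV (gtdb_name, ncbi_name)
#' @param path file path.
#' @return data.frame.
#' @export
read_name_map <- function(path) {
  .read_strict(path, "\t", c("gtdb_name", "ncbi_name"))
}

#' Read a bile-acid concentration matrix CSV
#'
#' First column sample id, second column group label, remaining columns BA
#' names; values in nmol/L.
#'
#' @param path file path.
#' @return list with `values` (numeric matrix, samples x BAs), `groups`.
#' @export
read_concentration_matrix <- function(path) {
  d <- .read_strict(path, ",", NULL)
  if (ncol(d) < 3) stop("concentration matrix needs sample, group and >= 1 BA")
  values <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- d[[1]]
  list(values = values, groups = d[[2]])
}

#' Write a bile-acid concentration matrix CSV
#'
#' @param values numeric matrix, samples x BAs.
#' @param groups group labels, length nrow(values).
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @param force overwrite an existing file.
#' @param ascii transliterate Greek letters in BA names.
#' @return the path, invisibly.
#' @export
write_concentration_matrix <- function(values, groups, path, seed = NULL,
                                       force = FALSE, ascii = FALSE) {
  d <- data.frame(sample = rownames(values), group = groups,
                  as.data.frame(values), check.names = FALSE,
                  stringsAsFactors = FALSE)
  .write_table(d, path, ",", seed = seed, force = force, ascii = ascii)
}

#' Write a generic TSV with a provenance header
#'
#' @param d data.frame.
#' @inheritParams write_concentration_matrix
#' @return the path, invisibly.
#' @export
write_tsv <- function(d, path, seed = NULL, force = FALSE, ascii = FALSE) {
  .write_table(d, path, "\t", seed = seed, force = force, ascii = ascii)
}

#' Write a biotransformation graph as edge-list TSV and JSON
#'
#' @param graph a "ba_graph" from [enumerate_edges()].
#' @param path edge-list TSV path; a ".json" sibling is written alongside.
#' @inheritParams write_concentration_matrix
#' @return the TSV path, invisibly.
#' @export
write_graph <- function(graph, path, seed = NULL, force = FALSE) {
  stopifnot(inherits(graph, "ba_graph"))
  .write_table(graph$edges, path, "\t", seed = seed, force = force)
  jpath <- sub("\\.tsv$", ".json", path)
  if (jpath == path) jpath <- paste0(path, ".json")
  if (file.exists(jpath) && !force) {
    stop("refusing to overwrite ", jpath, " (use force = TRUE)")
  }
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                       jpath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
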