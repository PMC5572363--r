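# Readers and writers for the plain-text formats used by the pipeline:
# the MSTMap-style genotype dialect, tab-separated genetic maps, truth
# tables and cluster reports.

mstmap_header_keys <- c("population_type", "population_name",
                        "distance_function", "cut_off_p_value",
                        "no_map_dist", "no_map_size", "missing_threshold",
                        "number_of_loci", "number_of_individual")

#' Read a genotype matrix in the MSTMap text dialect
#'
#' Parses a header of `key value` lines (population_type,
#' population_name, distance_function, cut_off_p_value, no_map_dist,
#' no_map_size, missing_threshold, number_of_loci,
#' number_of_individual), followed by one row per marker: the marker
#' identifier then whitespace-separated calls. `A`/`B` (case
#' insensitive) are the parental calls; `U` and `-` both denote a
#' missing call. A comment line starting `#individuals` may carry line
#' identifiers. Declared marker and individual counts are validated
#' against the parsed dimensions.
#'
#' @param path input file.
#' @return character call matrix lines x markers, with the parsed
#'   header as attribute `header`.
#' @export
read_genotypes_mstmap <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  header <- list()
  line_names <- NULL
  geno_rows <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#individuals")) {
      line_names <- strsplit(ln, "[ \t]+")[[1]][-1]
      next
    }
    if (startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (tok[1] %in% mstmap_header_keys && length(tok) == 2) {
      header[[tok[1]]] <- tok[2]
      next
    }
    calls <- toupper(tok[-1])
    calls[calls == "-"] <- "U"
    bad <- !(calls %in% c("A", "B", "U"))
    if (any(bad))
      stop("line ", k, ": unknown call symbol(s) ",
           paste(unique(tok[-1][bad]), collapse = " "))
    geno_rows[[tok[1]]] <- calls
  }
  if (!is.null(header$population_type) &&
      toupper(header$population_type) != "DH")
    stop("population_type must be DH, got ", header$population_type)
  if (length(geno_rows) == 0) stop("no marker rows found in ", path)
  n_ind <- unique(lengths(geno_rows))
  if (length(n_ind) != 1)
    stop("marker rows have differing numbers of calls")
  if (!is.null(header$number_of_loci) &&
      as.integer(header$number_of_loci) != length(geno_rows))
    stop("header declares ", header$number_of_loci, " loci but file has ",
         length(geno_rows))
  if (!is.null(header$number_of_individual) &&
      as.integer(header$number_of_individual) != n_ind)
    stop("header declares ", header$number_of_individual,
         " individuals but file has ", n_ind)
  geno <- do.call(cbind, geno_rows)
  rownames(geno) <- if (!is.null(line_names) && length(line_names) == n_ind)
    line_names else sprintf("line_%03d", seq_len(n_ind))
  attr(geno, "header") <- header
  geno
}

#' Write a genotype matrix in the MSTMap text dialect
#'
#' Writes the header, a `#individuals` comment carrying line names (so
#' a read/write round trip reproduces the matrix exactly, missing mask
#' included), then one row per marker.
#'
#' @param geno character call matrix.
#' @param path output file.
#' @param population_name,distance_function,cut_off_p_value,no_map_dist,
#'   no_map_size,missing_threshold header fields, defaulting to the
#'   stringent high-density settings used throughout the package.
#' @return `path`, invisibly.
#' @export
write_genotypes_mstmap <- function(geno, path,
                                   population_name = "simulated_pop",
                                   distance_function = "kosambi",
                                   cut_off_p_value = 1e-10,
                                   no_map_dist = 15.0, no_map_size = 2,
                                   missing_threshold = 0.10) {
  check_geno(geno)
  if (nrow(geno) == 0 || ncol(geno) == 0)
    stop("refusing to write an empty genotype matrix")
  header <- c(paste("population_type", "DH"),
              paste("population_name", population_name),
              paste("distance_function", distance_function),
              paste("cut_off_p_value", format(cut_off_p_value)),
              paste("no_map_dist", format(no_map_dist)),
              paste("no_map_size", format(no_map_size)),
              paste("missing_threshold", format(missing_threshold)),
              paste("number_of_loci", ncol(geno)),
              paste("number_of_individual", nrow(geno)),
              "",
              paste(c("#individuals", rownames(geno)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(geno)), function(j)
    paste(c(colnames(geno)[j], geno[, j]), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a genetic map as tab-separated text
#'
#' Columns lg, marker, position_cM (fixed 3 decimals).
#'
#' @param map `genetic_map` data frame (one or more LGs).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  out <- data.frame(lg = map$lg, marker = map$marker,
                    position_cM = sprintf("%.3f", map$position_cM),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map written by [write_map()]
#'
#' @param path input file.
#' @return a `genetic_map` data frame.
#' @export
read_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lg", "marker", "position_cM") %in% names(map)))
  class(map) <- c("genetic_map", "data.frame")
  attr(map, "length_cM") <- map_length(map)
  map
}

#' Write the simulator's truth table
#'
#' Tab-separated columns marker, lg, true_position_cM, cluster_id.
#'
#' @param truth truth data frame from [simulate_dh_population()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster report
#'
#' Tab-separated columns marker, lg_id, cluster_id, is_delegate, PIC,
#' missing_fraction.
#'
#' @param clusters `cluster_set` with delegates selected.
#' @param path output file.
#' @param lg_id linkage-group label.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path, lg_id = "LG1") {
  out <- data.frame(marker = clusters$marker, lg_id = lg_id,
                    cluster_id = clusters$cluster_id,
                    is_delegate = clusters$is_delegate,
                    PIC = sprintf("%.4f", clusters$pic),
                    missing_fraction = sprintf("%.4f",
                                               clusters$missing_frac),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
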