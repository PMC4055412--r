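#' Read and write the package's tab-separated table dialects
#'
#' All tables are tab-separated with a header row; missing values are empty
#' fields; protein identifiers are opaque strings. The intensity table has
#' `protein_id` followed by `<cell_line>.<replicate>` sample columns; the
#' homology table has `protein_id` and a comma-separated `species` column;
#' pathway, edge and mutation tables use the column schemas of
#' [generate_pathways()], [generate_edges()] and [generate_mutations()].
#'
#' @param path File path.
#' @return A tibble (readers) or the path, invisibly (writers).
#' @name world_io
NULL

#' @rdname world_io
#' @export
read_intensity_tsv <- function(path) {
  out <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(protein_id = "c",
                                                 .default = "d"))
  stopifnot("protein_id" %in% names(out))
  out
}

#' @rdname world_io
#' @param matrix Intensity tibble.
#' @export
write_intensity_tsv <- function(matrix, path) {
  readr::write_tsv(matrix, path, na = "")
  invisible(path)
}

#' @rdname world_io
#' @export
read_homology_tsv <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' @rdname world_io
#' @export
read_pathway_tsv <- function(path) {
  validate_pathway_table(
    readr::read_tsv(path, na = "", show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  )
}

#' @rdname world_io
#' @export
read_edge_tsv <- function(path) {
  as_edge_list(readr::read_tsv(path, na = "", show_col_types = FALSE,
                               col_types = readr::cols(.default = "c")))
}

#' @rdname world_io
#' @export
read_mutation_tsv <- function(path) {
  validate_mutation_counts(
    readr::read_tsv(path, na = "", show_col_types = FALSE,
                    col_types = readr::cols(protein_id = "c", .default = "i"))
  )
}

#' Write a synthetic world to a directory
#'
#' Writes the six input tables (`intensities.tsv`, `homology.tsv`,
#' `tree.nwk`, `pathways.tsv`, `edges.tsv`, `mutations.tsv`) plus a
#' `truth.json` of planted parameters and a `truth_proteins.tsv` of the
#' per-protein latent table.
#'
#' @param world A `bowtie_world` from [generate_world()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "bowtie_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_intensity_tsv(world$intensities, p("intensities.tsv"))
  readr::write_tsv(world$homology, p("homology.tsv"), na = "")
  write_species_tree(world$tree, p("tree.nwk"))
  readr::write_tsv(world$pathways, p("pathways.tsv"), na = "")
  readr::write_tsv(world$edges, p("edges.tsv"), na = "")
  readr::write_tsv(world$mutations, p("mutations.tsv"), na = "")
  readr::write_tsv(world$truth$proteins, p("truth_proteins.tsv"), na = "")
  truth <- world$truth
  jsonlite::write_json(
    list(config = unclass(truth$config),
         mutation_rates = truth$mutation_rates),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a world directory back into memory
#'
#' Reads the six tables written by [write_world()] (the truth files are
#' optional and ignored), returning a `bowtie_world`-shaped list without the
#' `truth` element.
#'
#' @param dir Directory containing the tables.
#' @return List with `intensities`, `homology`, `tree`, `pathways`, `edges`,
#'   `mutations`.
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    intensities = read_intensity_tsv(p("intensities.tsv")),
    homology = read_homology_tsv(p("homology.tsv")),
    tree = read_species_tree(p("tree.nwk")),
    pathways = read_pathway_tsv(p("pathways.tsv")),
    edges = read_edge_tsv(p("edges.tsv")),
    mutations = read_mutation_tsv(p("mutations.tsv"))
  )
}
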