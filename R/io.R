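#' Read a gene-leaf to species-leaf mapping
#'
#' The file dialect is a strict two-column tab-separated table with no header:
#' \code{geneLeaf<TAB>speciesLeaf}, one pair per line.  Blank lines and lines
#' starting with \code{#} are ignored.  The mapping need not be one-to-one nor
#' onto; totality and image containment are checked when the mapping is
#' assembled into a \code{\link{DTLInstance}}.
#'
#' @param file path to the mapping file, or \code{NULL} if \code{text} given.
#' @param text mapping content as a single string or character vector of lines.
#' @return named character vector: names are gene leaves, values species
#'   leaves.
#' @examples
#' readLeafMapping(text = "a\tA\nc\tC\n")
#' @export
readLeafMapping <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines)) stop("mapping is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("mapping line ", bad[1L],
         " is not a two-column tab-separated pair: '", lines[bad[1L]], "'",
         call. = FALSE)
  genes <- vapply(parts, `[`, character(1), 1L)
  species <- vapply(parts, `[`, character(1), 2L)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene leaf in mapping: '", dup[1L], "'", call. = FALSE)
  stats::setNames(species, genes)
}

#' Write a leaf mapping as two-column TSV
#' @param mapping named character vector (gene leaf -> species leaf).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeLeafMapping <- function(mapping, file) {
  writeLines(paste(names(mapping), mapping, sep = "\t"), file)
  invisible(file)
}

#' Write a DTLInstance to Newick + TSV files
#'
#' @param inst a \code{DTLInstance}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector with the three paths written.
#' @export
writeInstanceFiles <- function(inst, dir, prefix = "instance") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, paste0(prefix, ".species.nwk"))
  gn <- file.path(dir, paste0(prefix, ".gene.nwk"))
  mp <- file.path(dir, paste0(prefix, ".mapping.tsv"))
  writeLines(writeNewickTree(speciesTree(inst)), sp)
  writeLines(writeNewickTree(geneTree(inst)), gn)
  writeLeafMapping(leafMapping(inst), mp)
  c(species = sp, gene = gn, mapping = mp)
}

#' Read a DTLInstance from Newick + TSV files
#' @param species,gene paths to Newick files.
#' @param mapping path to the two-column TSV leaf mapping.
#' @param costs numeric event costs (duplication, transfer, loss).
#' @return a validated \code{DTLInstance}.
#' @export
readInstanceFiles <- function(species, gene, mapping, costs) {
  for (p in c(species, gene, mapping)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  DTLInstance(readNewickTree(species), readNewickTree(gene),
              readLeafMapping(mapping), costs)
}
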