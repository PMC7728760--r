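# End-to-end pipeline: graph -> blocks -> alignment.

#' Run the full collinear-block pipeline
#'
#' Builds the comprehensive de Bruijn graph of the input genomes,
#' detects junctions, applies abundance pruning, compacts the graph,
#' finds collinear blocks, and (unless skipped) aligns each block.
#' Writes `blocks.gff` always, `alignment.maf` unless
#' `skip_alignment`, and a JSON run manifest. Reruns with identical
#' inputs and parameters produce byte-identical outputs.
#'
#' @param inputs a [genome_set()], or a named character vector of FASTA
#'   paths (names become genome ids).
#' @param out_dir output directory (created if missing).
#' @param k k-mer size. Recommended defaults: 25 for large complex
#'   genomes, 15 for small ones (`preset`).
#' @param b maximum bubble side length (underlying edges).
#' @param m minimum block length (underlying edges).
#' @param a abundance pruning threshold.
#' @param batch_size seed batch size (result is batch-size invariant).
#' @param skip_alignment if `TRUE`, stop after block finding.
#' @param preset `"bacterial"` (k = 15) or `"mammalian"` (k = 25);
#'   overrides `k` when given.
#' @return (invisibly) list with `graph`, `result`, `blocks`,
#'   `aligned` (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(inputs, out_dir, k = 25, b = 200, m = 50, a = 150,
                         batch_size = 1L, skip_alignment = FALSE,
                         preset = NULL) {
  if (!is.null(preset)) {
    k <- switch(match.arg(preset, c("bacterial", "mammalian")),
                bacterial = 15L, mammalian = 25L)
  }
  genomes <- if (inherits(inputs, "genome_set")) inputs else {
    if (length(inputs) == 0L) stop_param("no input genomes")
    ids <- names(inputs) %||% sub("\\.(fa|fasta|fna)$", "", basename(inputs))
    read_genomes(inputs, ids)
  }
  if (max(genomes$length) <= k) stop_param("k (", k, ") is not smaller than the longest contig")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gff_path <- file.path(out_dir, "blocks.gff")
  maf_path <- file.path(out_dir, "alignment.maf")
  manifest_path <- file.path(out_dir, "manifest.json")
  ok <- FALSE
  on.exit({
    if (!ok) unlink(c(gff_path, maf_path, manifest_path))
  })

  message("building comprehensive de Bruijn graph (k=", k, ")")
  g <- comprehensive_dbg(genomes, k)
  junc <- find_junctions(g)
  junc <- prune_abundance(junc, g, a)
  cg <- compact_graph(g, junc)
  message("graph: ", length(cg$vertices), " junction k-mers, ",
          nrow(cg$edges), " compacted edges")

  message("finding collinear blocks (b=", b, ", m=", m, ")")
  res <- find_collinear_blocks(cg, b = b, m = m, batch_size = batch_size)
  blocks <- res$records
  write_blocks_gff(blocks, gff_path)
  message(length(unique(blocks$block_id)), " block(s), coverage ",
          sprintf("%.3f", block_coverage(blocks, genomes)))

  aligned <- NULL
  if (!skip_alignment) {
    message("aligning blocks")
    aligned <- align_all(blocks, genomes)
    write_maf(aligned, maf_path)
  }

  manifest <- list(
    tool = "lcblocks", version = as.character(utils::packageVersion("lcblocks")),
    parameters = list(k = k, b = b, m = m, a = a, batch_size = batch_size,
                      skip_alignment = skip_alignment),
    genomes = stats::setNames(as.list(genomes$length),
                              paste(genomes$genome_id, genomes$seq_id, sep = ".")),
    n_blocks = length(unique(blocks$block_id)),
    coverage = block_coverage(blocks, genomes))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(list(graph = cg, result = res, blocks = blocks, aligned = aligned,
                 paths = list(gff = gff_path,
                              maf = if (skip_alignment) NULL else maf_path,
                              manifest = manifest_path)))
}
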