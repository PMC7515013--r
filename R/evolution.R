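# Generational genetic algorithm, line-of-descent reconstruction and the
# elite-performer criterion.

#' Tournament selection
#'
#' Draws `tournament_size` individuals uniformly with replacement and
#' returns the index of the fittest; ties are broken uniformly at random.
#'
#' @param fitness numeric fitness vector of the population.
#' @param tournament_size number of contestants (default 2).
#' @return 1-based index of the selected parent.
#' @export
tournament_select <- function(fitness, tournament_size = 2L) {
  stopifnot(length(fitness) >= 1)
  cpp_tournament_select(as.numeric(fitness), as.integer(tournament_size))
}

#' Run evolution
#'
#' Generational GA: each generation every individual is evaluated on the
#' configured set of action-to-result mappings (fitness = Gtotal), the next
#' generation is produced by tournament selection plus mutation, and the
#' full ancestry (id, parent, fitness, genome hash) is archived. Genomes of
#' all ancestors of the final population are retained so the line of descent
#' can be reconstructed with genomes.
#'
#' @param config an experiment configuration, see [desk_profile()].
#' @param world a `grid_world`; built from the config when `NULL`.
#' @param init_genomes optional list of starting genomes (resume support);
#'   defaults to fresh [random_genome()]s.
#' @return an `evolution_archive`: `archive` data frame (generation, id,
#'   parent_id, fitness, genome_hash), `final_ids`, `genomes` (named list,
#'   ancestors of the final population), `world`, `config`.
#' @export
run_evolution <- function(config = desk_profile(), world = NULL,
                          init_genomes = NULL) {
  if (is.null(world)) {
    world <- build_world(config$world_width, config$world_height,
                         config$obstacle_fraction, config$spawn_distance)
  }
  if (is.null(init_genomes)) {
    init_genomes <- replicate(config$population_size,
                              random_genome(config$genome_length),
                              simplify = FALSE)
  }
  maps <- action_mappings()
  fit_maps <- maps[config$fitness_mappings, , drop = FALSE]
  out <- cpp_evolve(init_genomes, world, fit_maps,
                    as.integer(config$lifetime),
                    as.integer(config$generations),
                    as.integer(config$n_nodes),
                    .enabled_type_ids(config$gate_set),
                    TRUE,
                    as.integer(config$tournament_size),
                    config$mutation$point, config$mutation$duplication,
                    config$mutation$deletion,
                    .genome_len_min, .genome_len_max)
  genomes <- setNames(out$store_genomes, as.character(out$store_ids))
  arch <- list(archive = data.frame(generation = out$generation,
                                    id = out$id, parent_id = out$parent_id,
                                    fitness = out$fitness,
                                    genome_hash = out$genome_hash),
               final_ids = out$final_ids, genomes = genomes,
               world = world, config = config)
  class(arch) <- "evolution_archive"
  arch
}

#' @export
print.evolution_archive <- function(x, ...) {
  gmax <- max(x$archive$generation)
  last <- x$archive[x$archive$generation == gmax, ]
  cat(sprintf("<evolution_archive> %d generations, population %d\n",
              gmax, length(x$final_ids)))
  cat(sprintf("  final fitness: mean %.1f, best %.0f\n",
              mean(last$fitness), max(last$fitness)))
  invisible(x)
}

#' Reconstruct the line of descent
#'
#' Picks a uniformly random individual of the final generation and walks its
#' parent chain back to generation 0 (oldest first). Also reports the most
#' recent common ancestor (MRCA) of the whole final population: mutations
#' older than the MRCA have reached fixation.
#'
#' @param archive an `evolution_archive`.
#' @return a `line_of_descent`: `members` data frame (generation, id,
#'   parent_id, fitness, genome_hash), `genomes` (named list where
#'   retained), `mrca_id`, `mrca_generation`.
#' @export
line_of_descent <- function(archive) {
  a <- archive$archive
  parent <- setNames(a$parent_id, as.character(a$id))
  chain_of <- function(id) {
    chain <- integer(0)
    cur <- id
    while (cur >= 0) {
      chain <- c(chain, cur)
      nxt <- parent[as.character(cur)]
      if (is.na(nxt)) stop("broken parent pointer at id ", cur)
      cur <- nxt
    }
    rev(chain)
  }
  pick <- archive$final_ids[sample.int(length(archive$final_ids), 1)]
  lod_ids <- chain_of(pick)
  members <- a[match(lod_ids, a$id), ]
  rownames(members) <- NULL

  # MRCA: deepest id shared by every final individual's ancestor chain
  common <- chain_of(archive$final_ids[1])
  for (fid in archive$final_ids[-1]) {
    if (fid == archive$final_ids[1]) next
    common <- intersect(common, chain_of(fid))
  }
  mrca_id <- if (length(common)) common[length(common)] else NA_integer_
  mrca_gen <- if (!is.na(mrca_id)) {
    a$generation[match(mrca_id, a$id)]
  } else {
    NA_integer_
  }
  res <- list(members = members,
              genomes = archive$genomes[as.character(lod_ids)],
              picked_id = pick, mrca_id = mrca_id,
              mrca_generation = mrca_gen)
  class(res) <- "line_of_descent"
  res
}

#' @export
print.line_of_descent <- function(x, ...) {
  cat(sprintf("<line_of_descent> %d members, MRCA at generation %s\n",
              nrow(x$members), format(x$mrca_generation)))
  invisible(x)
}

#' Elite-performer test
#'
#' Evaluates a genome on all mappings with its internal feedback mechanism
#' enabled and disabled (same RNG state for both runs, so worlds and spawn
#' draws match), and applies the elite criterion: at least twice as many
#' goals with feedback as without, and a non-zero score.
#'
#' @param genome integer genome.
#' @param world a `grid_world`.
#' @param config experiment configuration (mappings, lifetime, decoding).
#' @return list with `g_total_learning`, `g_total_frozen`, `is_elite`.
#' @export
elite_filter <- function(genome, world, config = desk_profile()) {
  maps <- action_mappings()
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  seed_state <- get(".Random.seed", envir = globalenv())
  with_learning <- evaluate_all_mappings(
    genome, world, maps, config$lifetime, learning_enabled = TRUE,
    n_nodes = config$n_nodes, gate_set = config$gate_set)
  assign(".Random.seed", seed_state, envir = globalenv())
  frozen <- evaluate_all_mappings(
    genome, world, maps, config$lifetime, learning_enabled = FALSE,
    n_nodes = config$n_nodes, gate_set = config$gate_set)
  gl <- with_learning$g_total
  gf <- frozen$g_total
  list(g_total_learning = gl, g_total_frozen = gf,
       is_elite = gl > 0 && gl >= 2 * gf)
}

#' Export a line of descent as CSV
#' @param lod a `line_of_descent`.
#' @param path output file.
#' @export
write_lod_csv <- function(lod, path) {
  write.csv(lod$members[, c("generation", "fitness", "genome_hash")], path,
            row.names = FALSE)
}

#' Write an evolution archive as newline-delimited JSON
#'
#' One JSON record per generation (ids, parents, fitnesses, hashes),
#' preceded by a header record with the config hash; byte-stable for a given
#' archive.
#' @param archive an `evolution_archive`.
#' @param path output file.
#' @export
write_archive <- function(archive, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(
    list(type = "header", config_hash = config_hash(archive$config),
         population = length(archive$final_ids)),
    auto_unbox = TRUE, digits = NA)), con)
  for (g in sort(unique(archive$archive$generation))) {
    rows <- archive$archive[archive$archive$generation == g, ]
    writeLines(as.character(jsonlite::toJSON(
      list(type = "generation", generation = g, id = rows$id,
           parent_id = rows$parent_id, fitness = rows$fitness,
           genome_hash = rows$genome_hash),
      auto_unbox = TRUE, digits = NA)), con)
  }
  invisible(path)
}
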