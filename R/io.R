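# Plain-text dataset interchange: systems as long-format CSV, data points as
# CSV with terms encoded "label:coeff;...", splits as a JSON manifest.

#' Write / read an energy dataset directory
#'
#' Writes \code{systems.csv} (long format: label, rho, x2, w, quad_weight),
#' \code{offsets.csv}, \code{datapoints.csv} (id, data_type, weight,
#' reference_kcalmol, terms) and \code{splits.json}.
#'
#' @param dataset An \code{xc_energy_dataset}.
#' @param dir Directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sys_df <- do.call(rbind, lapply(dataset$systems, function(s) {
    data.frame(label = s$label, rho = s$rho, x2 = s$x2, w = s$w,
               quad_weight = s$quad_weights, stringsAsFactors = FALSE)
  }))
  write.csv(sys_df, file.path(dir, "systems.csv"), row.names = FALSE)
  write.csv(data.frame(label = names(dataset$offsets),
                       offset = unname(dataset$offsets)),
            file.path(dir, "offsets.csv"), row.names = FALSE)
  dp <- dataset$datapoints
  write.csv(data.frame(id = dp$id, data_type = dp$data_type,
                       weight = dp$weight, reference_kcalmol = dp$reference,
                       terms = dp$terms),
            file.path(dir, "datapoints.csv"), row.names = FALSE)
  splits <- split(dp$id, dp$split)
  writeLines(jsonlite::toJSON(splits, auto_unbox = FALSE, digits = NA),
             file.path(dir, "splits.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  sys_df <- read.csv(file.path(dir, "systems.csv"),
                     stringsAsFactors = FALSE)
  systems <- lapply(split(sys_df, sys_df$label), function(d) {
    new_grid_system(d$label[1], d$rho, d$x2, d$w, d$quad_weight)
  })
  off_df <- read.csv(file.path(dir, "offsets.csv"), stringsAsFactors = FALSE)
  offsets <- setNames(off_df$offset, off_df$label)
  dp <- read.csv(file.path(dir, "datapoints.csv"), stringsAsFactors = FALSE)
  splits <- jsonlite::fromJSON(file.path(dir, "splits.json"),
                               simplifyVector = TRUE)
  split_of <- rep(NA_character_, nrow(dp))
  for (s in names(splits)) split_of[dp$id %in% splits[[s]]] <- s
  datapoints <- data.frame(id = dp$id, data_type = dp$data_type,
                           weight = dp$weight,
                           reference = dp$reference_kcalmol,
                           terms = dp$terms, split = split_of,
                           stringsAsFactors = FALSE)
  new_energy_dataset(systems[unique(sys_df$label)], datapoints, offsets)
}

#' Persist / restore a population snapshot
#'
#' JSON array of individuals (functional, parameters, errors, insertion
#' index), enabling warm restarts of an evolution.
#'
#' @param population An \code{xc_population}.
#' @param path File path.
#' @export
population_save <- function(population, path) {
  recs <- lapply(population_members(population), function(ind) {
    list(functional = jsonlite::fromJSON(
           functional_to_json(ind$functional), simplifyVector = FALSE),
         params = as.list(ind$params), J_train = ind$J_train,
         J_val = ind$J_val, insertion_index = ind$insertion_index)
  })
  writeLines(jsonlite::toJSON(list(counter = population$counter,
                                   max_size = population$max_size,
                                   members = recs),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname population_save
#' @export
population_load <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                collapse = "\n"),
                          simplifyVector = FALSE)
  pop <- new_population(x$max_size)
  pop$counter <- as.integer(x$counter)
  pop$members <- lapply(x$members, function(rec) {
    fun <- new_functional(
      x = program_from_list(rec$functional$programs$x),
      c_ss = program_from_list(rec$functional$programs$c_ss),
      c_os = program_from_list(rec$functional$programs$c_os))
    new_individual(fun, unlist(rec$params), as.numeric(rec$J_train),
                   as.numeric(rec$J_val),
                   insertion_index = as.integer(rec$insertion_index))
  })
  pop
}
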