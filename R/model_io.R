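#' @include AllClasses.R
NULL

#' Construct a MetabolicModel from tabular pieces
#'
#' @param id model id.
#' @param metabolites data.frame with columns \code{id}, \code{name}
#'   (optional, defaults to id), \code{compartment}, and optionally
#'   \code{carbon} (atoms, for mass-balance audits).
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{is_exchange}, \code{is_biomass}.
#' @param stoichiometry named list of named numeric vectors (metabolite ->
#'   coefficient, negative = consumed), one entry per reaction id.
#' @param annotations optional list (e.g. \code{genome_size_bp},
#'   \code{rrna_copies}).
#' @return validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(id, metabolites, reactions, stoichiometry,
                           annotations = list()) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$carbon)) metabolites$carbon <- NA_real_
  metabolites$carbon <- as.numeric(metabolites$carbon)
  metabolites <- metabolites[, c("id", "name", "compartment", "carbon")]
  for (col in c("is_exchange", "is_biomass"))
    reactions[[col]] <- as.logical(reactions[[col]])
  bid <- reactions$id[reactions$is_biomass]
  if (length(bid) != 1)
    stop("model '", id, "' must have exactly one biomass reaction, found ",
         length(bid))
  new("MetabolicModel", id = id, metabolites = metabolites,
      reactions = reactions, stoichiometry = stoichiometry[reactions$id],
      biomassId = bid, annotations = annotations)
}

# "glc_c:-2;atp_c:-1;bio:1" -> named numeric
parseStoichiometry <- function(txt, where = "") {
  out <- lapply(seq_along(txt), function(i) {
    parts <- strsplit(trimws(txt[i]), ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0)
      stop("empty stoichiometry", where, " (record ", i, ")")
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2
    if (any(bad))
      stop("malformed stoichiometry term '", parts[bad][1], "'", where,
           " (record ", i, ")")
    coefs <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
    if (anyNA(coefs))
      stop("non-numeric stoichiometric coefficient", where, " (record ", i, ")")
    stats::setNames(coefs, trimws(vapply(kv, `[`, "", 1)))
  })
  out
}

formatStoichiometry <- function(s)
  paste(sprintf("%s:%.10g", names(s), unname(s)), collapse = ";")

#' Read and write metabolic models
#'
#' The native on-disk representation is either a single JSON document or a
#' directory with two TSVs, \code{metabolites.tsv} (id, name, compartment,
#' carbon) and \code{reactions.tsv} (id, stoichiometry as
#' \code{"met:coef;met:coef"}, lb, ub, is_exchange, is_biomass). A
#' read-only subset of SBML (species, reactions, bounds through parameters)
#' is supported for interoperability with other reconstruction tools; this
#' is deliberately not a full SBML FBC implementation.
#'
#' @param path file (json/sbml) or directory (tabular).
#' @param format one of "tabular", "json", "sbml"; default guesses from
#'   the path (directory -> tabular, .xml/.sbml -> sbml, else json).
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
readModel <- function(path, format = c("auto", "tabular", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tabular"
      else if (grepl("\\.(xml|sbml)$", path)) "sbml" else "json"
  }
  switch(format,
    tabular = readModelTabular(path),
    json = readModelJson(path),
    sbml = readModelSbml(path))
}

readModelTabular <- function(dir) {
  mf <- file.path(dir, "metabolites.tsv")
  rf <- file.path(dir, "reactions.tsv")
  if (!file.exists(mf) || !file.exists(rf))
    stop("tabular model needs ", mf, " and ", rf)
  met <- utils::read.delim(mf, stringsAsFactors = FALSE)
  rxn <- utils::read.delim(rf, stringsAsFactors = FALSE)
  need <- setdiff(c("id", "stoichiometry", "lb", "ub", "is_exchange",
                    "is_biomass"), names(rxn))
  if (length(need)) stop("reactions.tsv misses columns: ",
                         paste(need, collapse = ", "))
  st <- parseStoichiometry(rxn$stoichiometry, paste0(" in ", rf))
  names(st) <- rxn$id
  rxn$lb <- as.numeric(rxn$lb); rxn$ub <- as.numeric(rxn$ub)
  if (!is.null(met$carbon)) met$carbon <- as.numeric(met$carbon)
  ann <- list()
  af <- file.path(dir, "annotations.json")
  if (file.exists(af)) ann <- jsonlite::read_json(af, simplifyVector = TRUE)
  id <- if (!is.null(ann$id)) ann$id else basename(normalizePath(dir))
  m <- MetabolicModel(id, met, rxn[, setdiff(names(rxn), "stoichiometry")],
                      st, annotations = ann[setdiff(names(ann), "id")])
  validObject(m)
  m
}

readModelJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  for (f in c("id", "metabolites", "reactions"))
    if (is.null(doc[[f]])) stop("model JSON misses field '", f, "' in ", path)
  rx <- as.data.frame(doc$reactions)
  st <- parseStoichiometry(rx$stoichiometry, paste0(" in ", path))
  names(st) <- rx$id
  rx$lb <- as.numeric(rx$lb); rx$ub <- as.numeric(rx$ub)
  ann <- if (is.null(doc$annotations)) list() else as.list(doc$annotations)
  m <- MetabolicModel(doc$id, as.data.frame(doc$metabolites),
                      rx[, setdiff(names(rx), "stoichiometry")], st,
                      annotations = ann)
  validObject(m)
  m
}

readModelSbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML input needs the xml2 package")
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  compOf <- stats::setNames(met$compartment, met$id)
  rxn <- list(); st <- list()
  for (nd in rxn_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    reac <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sgn) {
      if (length(nodes) == 0) return(numeric())
      k <- xml2::xml_attr(nodes, "stoichiometry")
      k <- ifelse(is.na(k), 1, as.numeric(k))
      stats::setNames(sgn * k, xml2::xml_attr(nodes, "species"))
    }
    s <- c(coef(reac, -1), coef(prod, 1))
    lbref <- xml2::xml_attr(nd, "lowerFluxBound")
    ubref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lbref) && lbref %in% names(parval)) parval[[lbref]] else
      if (isTRUE(xml2::xml_attr(nd, "reversible") == "false")) 0 else -1000
    ub <- if (!is.na(ubref) && ubref %in% names(parval)) parval[[ubref]] else 1000
    rxn[[rid]] <- data.frame(id = rid, lb = lb, ub = ub,
      is_exchange = length(s) == 1 && s[1] == -1 &&
        identical(unname(compOf[names(s)]), "e"),
      is_biomass = grepl("biomass", rid, ignore.case = TRUE),
      stringsAsFactors = FALSE)
    st[[rid]] <- s
  }
  rxn <- do.call(rbind, rxn)
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  m <- MetabolicModel(if (is.na(mid)) basename(path) else mid, met, rxn, st)
  validObject(m)
  m
}

#' @rdname readModel
#' @param model a \linkS4class{MetabolicModel}.
#' @export
writeModel <- function(model, path, format = c("auto", "tabular", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "json" else "tabular"
  rxn <- model@reactions
  rxn$stoichiometry <- vapply(model@stoichiometry[rxn$id],
                              formatStoichiometry, "")
  rxn <- rxn[, c("id", "stoichiometry", "lb", "ub", "is_exchange", "is_biomass")]
  if (format == "tabular") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(model@metabolites, file.path(path, "metabolites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rxn, file.path(path, "reactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- c(list(id = model@id), model@annotations)
    jsonlite::write_json(ann, file.path(path, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    doc <- list(id = model@id, metabolites = model@metabolites,
                reactions = rxn, annotations = model@annotations)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Apply a growth medium to a model
#'
#' Sets the lower bound of every exchange reaction whose metabolite is in
#' the medium to minus its maximum uptake rate and closes uptake (lower
#' bound 0) through every other exchange. Secretion (upper) bounds are left
#' untouched. A medium metabolite with no exchange reaction in the model
#' triggers a warning, not an error. Idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{Medium}.
#' @return the model with adjusted exchange bounds.
#' @export
applyMedium <- function(model, medium) {
  stopifnot(is(model, "MetabolicModel"), is(medium, "Medium"))
  rxn <- model@reactions
  ex <- which(rxn$is_exchange)
  exmet <- vapply(model@stoichiometry[rxn$id[ex]],
                  function(s) names(s)[1], "")
  rxn$lb[ex] <- 0
  lim <- uptakeLimits(medium)
  hit <- match(names(lim), exmet)
  if (anyNA(hit))
    warning("medium '", medium@name, "' names metabolites without exchange: ",
            paste(names(lim)[is.na(hit)], collapse = ", "))
  ok <- !is.na(hit)
  rxn$lb[ex[hit[ok]]] <- -unname(lim[ok])
  model@reactions <- rxn
  model
}

#' Read tabular inputs: media, hit tables, pathways, plates, traits
#'
#' \code{readMedium}: CSV with columns \code{metabolite_id},
#' \code{max_uptake}. \code{readHitTable}: TSV with \code{genome_id},
#' \code{query_id}, \code{bitscore}, \code{qcovs}; coverage given as
#' percent is autodetected (any value > 1.5) and rescaled to a fraction.
#' \code{readPathways}: TSV with \code{pathway_id}, \code{name},
#' \code{reaction_ids}, \code{key_reaction_ids} (";"-separated) and
#' \code{category}. \code{readPlate}: CSV with \code{strain},
#' \code{substrate}, \code{replicate}, \code{time_min}, \code{od}; a
#' designated water control well is mandatory. \code{readTraits}: CSV of
#' per-isolate traits.
#'
#' @param path input file.
#' @param name medium name (defaults to file name).
#' @return validated objects: a \linkS4class{Medium} or data.frames.
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
readMedium <- function(path, name = sub("\\.[^.]+$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "max_uptake") %in% names(df)))
    stop("medium CSV needs columns metabolite_id, max_uptake: ", path)
  if (!is.numeric(df$max_uptake))
    stop("non-numeric max_uptake in ", path)
  Medium(name, stats::setNames(df$max_uptake, df$metabolite_id))
}

#' @rdname tabular-io
#' @param medium a \linkS4class{Medium} to serialise.
#' @export
writeMedium <- function(medium, path) {
  utils::write.csv(data.frame(metabolite_id = names(medium@uptake),
                              max_uptake = unname(medium@uptake)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
readHitTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("genome_id", "query_id", "bitscore", "qcovs"), names(df))
  if (length(need)) stop("hit table misses columns: ",
                         paste(need, collapse = ", "), " in ", path)
  if (!is.numeric(df$bitscore) || !is.numeric(df$qcovs))
    stop("non-numeric bitscore/qcovs in ", path)
  if (any(df$qcovs > 1.5)) {
    message("hit table ", basename(path),
            ": qcovs looks like percent, rescaling to fraction")
    df$qcovs <- df$qcovs / 100
  }
  if (any(df$bitscore < 0) || any(df$qcovs < 0 | df$qcovs > 1))
    stop("bitscore must be >= 0 and qcovs within [0,1] in ", path)
  df
}

#' @rdname tabular-io
#' @export
readPathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("pathway_id", "name", "reaction_ids", "key_reaction_ids",
                    "category"), names(df))
  if (length(need)) stop("pathway table misses columns: ",
                         paste(need, collapse = ", "), " in ", path)
  split_ids <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) trimws(v[nzchar(trimws(v))]))
  df$reaction_ids <- split_ids(df$reaction_ids)
  df$key_reaction_ids <- split_ids(df$key_reaction_ids)
  for (i in seq_len(nrow(df))) {
    if (length(df$reaction_ids[[i]]) == 0)
      stop("pathway '", df$pathway_id[i], "' has no reactions")
    extra <- setdiff(df$key_reaction_ids[[i]], df$reaction_ids[[i]])
    if (length(extra))
      stop("pathway '", df$pathway_id[i], "': key reactions not in pathway: ",
           paste(extra, collapse = ", "))
  }
  df
}

#' @rdname tabular-io
#' @param water_id substrate id of the water control well.
#' @export
readPlate <- function(path, water_id = "water") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("strain", "substrate", "replicate", "time_min", "od"),
                  names(df))
  if (length(need)) stop("plate CSV misses columns: ",
                         paste(need, collapse = ", "), " in ", path)
  if (!is.numeric(df$od) || !is.numeric(df$time_min))
    stop("non-numeric od/time_min in ", path)
  if (any(df$od < 0)) stop("negative OD in ", path)
  if (!water_id %in% df$substrate)
    stop("plate ", path, " has no '", water_id, "' control well")
  attr(df, "water_id") <- water_id
  df
}

#' @rdname tabular-io
#' @export
readTraits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"isolate_id" %in% names(df))
    stop("traits CSV needs an isolate_id column: ", path)
  df
}
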