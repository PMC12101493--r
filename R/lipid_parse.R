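#' Lipid class ontology
#'
#' Reads the editable class ontology shipped with the package (or a user
#' file in the same format): one row per headgroup class with its category
#' (phospholipid / glycolipid / betaine / neutral / other), phosphorus,
#' chloroplast and betaine flags, membrane membership and expected chain
#' count. The defaults follow the thylakoid convention that SQDG, MGDG,
#' DGDG and PG are chloroplast lipids, and treat DGTS and DGTA as the single
#' class "DGTS/A".
#'
#' @param path optional path to an ontology TSV; default is the shipped one.
#' @return data.frame with columns class, headgroup_category,
#'   has_phosphorus, is_chloroplast, is_betaine, is_membrane, n_chains.
#' @export
lipid_class_ontology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_class_ontology.tsv",
                        package = "eigenlipid")
  }
  ont <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("class", "headgroup_category", "has_phosphorus",
              "is_chloroplast", "is_betaine", "is_membrane", "n_chains")
  if (!all(needed %in% names(ont))) {
    stop("ontology file missing columns: ",
         paste(setdiff(needed, names(ont)), collapse = ", "))
  }
  ont
}

# normalize headgroup synonyms to ontology class codes
normalize_class <- function(cls) {
  cls <- toupper(trimws(cls))
  cls[cls %in% c("DGTS", "DGTA", "DGTS/A", "DGTS_A")] <- "DGTS/A"
  cls[cls == "TG"] <- "TAG"
  cls[cls == "DG"] <- "DAG"
  cls
}

#' Parse lipid shorthand names
#'
#' Accepts sum-composition names (\code{"PC 36:2"}) and chain-level names
#' (\code{"PC 16:0/20:5"}, \code{"TAG 16:0/18:1/18:2"}). The headgroup is
#' everything before the last whitespace; unknown headgroups are kept and
#' classified as \code{"other"}. TAG species have three acyl chains, all
#' other glycerolipid classes two.
#'
#' @param names character vector of shorthand names.
#' @param annotation_tier optional character vector (recycled) of annotation
#'   tiers ("Ann.1", "Ann.2", "Ann.3").
#' @param ontology ontology data.frame from \code{\link{lipid_class_ontology}}.
#' @return data.frame with one row per name: \code{id}, \code{name},
#'   \code{headgroup}, \code{annotation_tier}, \code{total_carbons},
#'   \code{total_double_bonds}, \code{n_chains}, \code{chains} (string like
#'   \code{"16:0/20:5"} or NA for sum compositions), \code{has_phosphorus},
#'   \code{is_chloroplast}, \code{is_betaine}, \code{is_membrane},
#'   \code{headgroup_category}.
#' @export
parse_lipid_name <- function(names, annotation_tier = "Ann.1",
                             ontology = lipid_class_ontology()) {
  if (length(names) == 0L) stop("no lipid names supplied")
  tier <- rep_len(annotation_tier, length(names))
  comp_rx <- "^[0-9]+:[0-9]+(/[0-9]+:[0-9]+){0,2}$"

  parse_one <- function(nm, tr) {
    nm <- trimws(nm)
    m <- regexpr("\\s+[0-9:/]+$", nm)
    if (m < 0) stop("unparseable lipid name: '", nm,
                    "' (no composition token)")
    cls <- normalize_class(substr(nm, 1L, m - 1L))
    comp <- trimws(substr(nm, m, nchar(nm)))
    if (!grepl(comp_rx, comp)) {
      stop("unparseable lipid name: '", nm, "' (bad composition token '",
           comp, "')")
    }
    row <- ontology[match(cls, ontology$class), ]
    if (is.na(row$class)) row <- ontology[ontology$class == "other", ]
    n_chains_expected <- if (cls == "TAG") 3L else as.integer(row$n_chains)

    parts <- strsplit(comp, "/", fixed = TRUE)[[1]]
    cd <- do.call(rbind, lapply(strsplit(parts, ":", fixed = TRUE),
                                as.integer))
    if (length(parts) > 1L) {           # chain-level annotation
      if (length(parts) != n_chains_expected) {
        stop("lipid '", nm, "': ", length(parts), " chains given but class ",
             cls, " has ", n_chains_expected)
      }
      total_c <- sum(cd[, 1]); total_db <- sum(cd[, 2])
      chains <- comp
      n_chains <- length(parts)
    } else {                            # sum composition
      total_c <- cd[1, 1]; total_db <- cd[1, 2]
      chains <- NA_character_
      n_chains <- n_chains_expected
    }
    if (total_c < 2L * n_chains) {
      stop("lipid '", nm, "': total carbons ", total_c,
           " below minimum for ", n_chains, " chains")
    }
    data.frame(name = nm, headgroup = if (is.na(row$class)) "other" else cls,
               annotation_tier = tr,
               total_carbons = total_c, total_double_bonds = total_db,
               n_chains = n_chains, chains = chains,
               has_phosphorus = row$has_phosphorus,
               is_chloroplast = row$is_chloroplast,
               is_betaine = row$is_betaine,
               is_membrane = row$is_membrane,
               headgroup_category = row$headgroup_category,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(parse_one, names, tier))
  rownames(out) <- NULL
  cbind(data.frame(id = names, stringsAsFactors = FALSE), out)
}

#' Canonical shorthand name of a parsed species
#' @param species one row (or several) of a \code{parse_lipid_name} result.
#' @return character vector of canonical names.
#' @export
format_lipid_name <- function(species) {
  ifelse(is.na(species$chains),
         sprintf("%s %d:%d", species$headgroup, species$total_carbons,
                 species$total_double_bonds),
         paste(species$headgroup, species$chains))
}

#' Saturation class of lipid species
#'
#' With chain-level data a species is PUFA-containing iff any chain carries
#' >= 2 double bonds. For sum compositions without chains the heuristic is
#' used: PUFA-containing iff total double bonds exceed the chain count
#' (otherwise the double bonds could be spread at <= 1 per chain); such
#' calls are flagged \code{heuristic = TRUE}.
#'
#' @param species data.frame from \code{\link{parse_lipid_name}}.
#' @return the input with columns \code{species_class} ("SFA/MUFA" or
#'   "PUFA-containing"), \code{has_epa} (any 20:5 chain) and
#'   \code{heuristic} appended.
#' @export
classify_saturation <- function(species) {
  has_chains <- !is.na(species$chains)
  max_db <- rep(NA_integer_, nrow(species))
  has_epa <- rep(FALSE, nrow(species))
  if (any(has_chains)) {
    parsed <- lapply(species$chains[has_chains], function(ch) {
      do.call(rbind, lapply(strsplit(strsplit(ch, "/")[[1]], ":"),
                            as.integer))
    })
    max_db[has_chains] <- vapply(parsed, function(m) max(m[, 2]), integer(1))
    has_epa[has_chains] <- vapply(parsed, function(m) {
      any(m[, 1] == 20L & m[, 2] == 5L)
    }, logical(1))
  }
  pufa <- ifelse(has_chains,
                 max_db >= 2L,
                 species$total_double_bonds > species$n_chains)
  species$species_class <- ifelse(pufa, "PUFA-containing", "SFA/MUFA")
  species$has_epa <- has_epa
  species$heuristic <- !has_chains
  species
}

#' Per-chain saturation label
#' @param carbons,double_bonds integer vectors describing chains.
#' @return character vector: "SFA" (0 double bonds), "MUFA" (1),
#'   "PUFA" (>= 2).
#' @export
chain_saturation <- function(carbons, double_bonds) {
  ifelse(double_bonds == 0L, "SFA", ifelse(double_bonds == 1L, "MUFA", "PUFA"))
}

#' Intensity-weighted mean chain length (carbons per fatty acid)
#'
#' For each sample, the intensity-weighted mean of total carbons divided by
#' chain count over a selected species set:
#' \eqn{\sum_i w_i (C_i/n_i) / \sum_i w_i}.
#'
#' @param features \code{feature_table} (any view with non-negative weights,
#'   normally raw or relative intensities).
#' @param species parsed species table aligned to \code{rownames(features)}
#'   via its \code{id} column.
#' @param select logical vector over features (or character vector of ids)
#'   choosing the species set, e.g. membrane glycerolipids of one
#'   saturation class.
#' @return named numeric vector over samples; NA where the selected set has
#'   zero total intensity.
#' @export
weighted_mean_chain_length <- function(features, species, select) {
  if (is.character(select)) select <- rownames(features) %in% select
  if (!any(select)) stop("empty species selection for chain-length summary")
  idx <- match(rownames(features)[select], species$id)
  if (anyNA(idx)) stop("species table does not cover all selected features")
  cpf <- species$total_carbons[idx] / species$n_chains[idx]
  w <- as_ft_matrix(features)[select, , drop = FALSE]
  tot <- colSums(w)
  out <- colSums(w * cpf) / tot
  out[tot <= 0] <- NA_real_
  out
}
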