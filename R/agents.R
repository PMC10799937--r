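#' Read a damage-agent hierarchy table
#'
#' Four-column CSV (`level4`, `level3`, `level2`, `level1`) mapping each
#' detailed (level-4) agent code to progressively coarser categories. A
#' 10-code demo hierarchy ships with the package
#' (`system.file("extdata", "agent_hierarchy.csv", package = "snagmap")`);
#' operational users supply their own table.
#'
#' @param path CSV path; default is the bundled demo hierarchy.
#' @return tibble with the four level columns.
#' @export
read_agent_hierarchy <- function(path = system.file(
  "extdata", "agent_hierarchy.csv", package = "snagmap")) {
  h <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("level4", "level3", "level2", "level1") %in% names(h)))
  if (anyDuplicated(h$level4)) stop("duplicate level4 codes in hierarchy")
  h
}

#' Resolve the agents of an overlap between two survey polygons
#'
#' Year precedence: the overlap carries the agents of the later survey
#' (mortality is re-reported each year, so the latest record supersedes).
#' Equal years take the union of the two agent lists, code-sorted and
#' truncated to three.
#'
#' @param agents1,agents2 character vectors of level-4 codes.
#' @param year1,year2 survey years.
#' @return character vector of resolved codes.
#' @export
resolve_survey_overlap <- function(agents1, year1, agents2, year2) {
  if (year1 > year2) return(agents1)
  if (year2 > year1) return(agents2)
  utils::head(sort(union(agents1, agents2)), 3L)
}

#' Resolve the agents of an overlap between a survey region and a fire
#'
#' A fire in or after the survey year adds `"fire"` to the survey agents
#' (the burn can plausibly have killed the trees); an older fire leaves the
#' survey record unchanged. The union may carry four codes (three survey
#' agents plus fire); this is allowed.
#'
#' @param survey_agents character vector of level-4 codes (may be empty).
#' @param survey_year survey year (use `-Inf` for fire-only regions).
#' @param fire_year year of the fire perimeter.
#' @return character vector of resolved codes.
#' @export
resolve_fire_overlap <- function(survey_agents, survey_year, fire_year) {
  if (fire_year >= survey_year) sort(union(survey_agents, "fire"))
  else survey_agents
}

# Agents of the resolved planar partition at one point: among covering
# survey polygons the latest year wins (equal years union, truncated to 3);
# any covering fire with year >= that survey year appends "fire".
agents_at_point <- function(x, y, layers) {
  covering <- vapply(layers$geometry, function(g)
    is.matrix(g) && point_in_poly(x, y, g), TRUE)
  surv <- which(covering & layers$kind == "survey")
  fire <- which(covering & layers$kind == "fire")
  agents <- character(0)
  year <- -Inf
  if (length(surv)) {
    year <- max(layers$year[surv])
    top <- surv[layers$year[surv] == year]
    agents <- utils::head(
      sort(unique(unlist(layers$agents[top]))), 3L)
  }
  if (length(fire) && any(layers$year[fire] >= year))
    agents <- sort(union(agents, "fire"))
  list(agents = agents, year = if (length(surv) || length(fire)) {
    max(c(layers$year[surv], layers$year[fire]))
  } else NA_integer_)
}

#' Attribute damage agents to crowns by polygon overlay
#'
#' Each crown takes the agents of the resolved agent map at its centroid
#' (a tree has one death and one location, so pointwise attribution is used
#' rather than area weighting). The resolved map applies the survey
#' year-precedence rule and the fire rule; the result is independent of the
#' input order of layers. Crowns outside all polygons stay unattributed.
#' Level-3/2/1 rollups are attached via the hierarchy table.
#'
#' @param crowns a `crown_records` tibble.
#' @param layers a `vector_layer` of agent polygons with `year`, `agents`
#'   (list-column or semicolon-separated string) and `kind`
#'   (`"survey"`/`"fire"`) columns.
#' @param hierarchy tibble from [read_agent_hierarchy()].
#' @return `crowns` with `agents` (list-column), `agent_year`, and
#'   `level3`/`level2`/`level1` list-columns of rollup codes.
#' @export
attribute_crowns <- function(crowns, layers,
                             hierarchy = read_agent_hierarchy()) {
  layers <- normalise_agent_layers(layers)
  res <- lapply(seq_len(nrow(crowns)), function(i)
    agents_at_point(crowns$cx[i], crowns$cy[i], layers))
  rollup <- function(codes, level) {
    if (!length(codes)) return(character(0))
    i <- match(codes, hierarchy$level4)
    sort(unique(ifelse(is.na(i), "unknown", hierarchy[[level]][i])))
  }
  out <- tibble::as_tibble(crowns)
  out$agents <- lapply(res, `[[`, "agents")
  out$agent_year <- vapply(res, function(r) as.integer(r$year), 1L)
  out$level3 <- lapply(out$agents, rollup, level = "level3")
  out$level2 <- lapply(out$agents, rollup, level = "level2")
  out$level1 <- lapply(out$agents, rollup, level = "level1")
  structure(out, crs = attr(crowns, "crs"), px = attr(crowns, "px"),
            class = class(crowns))
}

normalise_agent_layers <- function(layers) {
  stopifnot(all(c("year", "agents", "kind") %in% names(layers)))
  tab <- tibble::as_tibble(layers)
  if (!is.list(tab$agents))
    tab$agents <- strsplit(as.character(tab$agents), ";", fixed = TRUE)
  bad <- tab$kind == "survey" &
    !vapply(tab$agents, function(a) length(a) >= 1 && length(a) <= 3, TRUE)
  if (any(bad)) stop("survey polygons must carry 1-3 agent codes")
  tab$year <- as.numeric(tab$year)
  tab
}

#' Summarise attributed crowns by agent category
#'
#' Counts crowns per observed agent combination (a combination such as
#' bark beetle + fire is its own row, not double-counted in the singles)
#' at the requested category level, with percentages against all crowns and
#' against attributed crowns.
#'
#' @param crowns attributed `crown_records` (from [attribute_crowns()]).
#' @param level one of `"agents"` (level 4), `"level3"`, `"level2"`,
#'   `"level1"`.
#' @return tibble `category` (combination string, " + "-separated),
#'   `n`, `pct_of_total`, `pct_of_attributed`; attributes `n_total`,
#'   `n_attributed`.
#' @export
agent_summary <- function(crowns, level = c("agents", "level3", "level2",
                                            "level1")) {
  level <- match.arg(level)
  codes <- crowns[[level]]
  lab <- vapply(codes, function(a)
    if (length(a)) paste(a, collapse = " + ") else NA_character_, "x")
  n_total <- length(lab)
  n_attr <- sum(!is.na(lab))
  tab <- tibble::tibble(category = lab[!is.na(lab)]) |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  tab$pct_of_total <- if (n_total) 100 * tab$n / n_total else numeric(0)
  tab$pct_of_attributed <- if (n_attr) 100 * tab$n / n_attr else numeric(0)
  structure(tab, n_total = n_total, n_attributed = n_attr,
            attributed_pct = if (n_total) 100 * n_attr / n_total else NA_real_)
}
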