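# Domain types and I/O: state classification, panels, networks, filtering,
# transition extraction.

#' Moderate-to-heavy drinking cutoff policy
#'
#' Thresholds (drinks per week) separating moderate from heavy drinking.
#' The defaults are the NIAAA cutoffs: 7 drinks/week for women and 14 for
#' men. In cutoff sweeps the male threshold is constrained to twice the
#' female one.
#'
#' @param female_threshold numeric > 0, drinks/week for women (default 7).
#' @param male_threshold numeric > 0, drinks/week for men (default
#'   `2 * female_threshold`).
#' @return an object of class `cutoff_policy`.
#' @export
cutoff_policy <- function(female_threshold = 7, male_threshold = 2 * female_threshold) {
  stopifnot(is.numeric(female_threshold), female_threshold > 0,
            is.numeric(male_threshold), male_threshold > 0)
  structure(list(female_threshold = female_threshold,
                 male_threshold = male_threshold),
            class = "cutoff_policy")
}

#' @export
print.cutoff_policy <- function(x, ...) {
  cat(sprintf("Cutoff policy: moderate/heavy at %g (women) / %g (men) drinks per week\n",
              x$female_threshold, x$male_threshold))
  invisible(x)
}

#' Classify drinks per week into drinking states
#'
#' Zero drinks is abstinent (A); more than zero and up to the sex-specific
#' threshold (inclusive) is moderate (M); strictly above the threshold is
#' heavy (H). Missing drinks or sex yields `NA` (the record is flagged and
#' excluded downstream, never imputed).
#'
#' @param drinks_per_week non-negative numeric vector (NA allowed).
#' @param sex character vector in `c("female", "male")` (NA allowed).
#' @param policy a [cutoff_policy()].
#' @return character vector in `c("A", "M", "H")` with `NA` where undefined.
#' @examples
#' classify_state(c(0, 7, 14.5), c("male", "female", "male"), cutoff_policy())
#' @export
classify_state <- function(drinks_per_week, sex, policy = cutoff_policy()) {
  stopifnot(inherits(policy, "cutoff_policy"))
  n <- max(length(drinks_per_week), length(sex))
  drinks <- rep_len(as.numeric(drinks_per_week), n)
  sex <- rep_len(as.character(sex), n)
  bad_sex <- !(sex %in% c("female", "male")) & !is.na(sex)
  if (any(bad_sex)) stop("sex must be 'female' or 'male' (or NA)")
  if (any(drinks < 0, na.rm = TRUE)) stop("drinks_per_week must be non-negative")
  thr <- ifelse(sex == "female", policy$female_threshold, policy$male_threshold)
  out <- rep(NA_character_, n)
  ok <- !is.na(drinks) & !is.na(sex)
  out[ok & drinks == 0] <- "A"
  out[ok & drinks > 0 & drinks <= thr] <- "M"
  out[ok & drinks > thr] <- "H"
  out
}

#' Build a longitudinal state panel
#'
#' Validates per-person, per-wave observations, derives the drinking state
#' under `policy` and attaches wave metadata (midpoint year and the interval
#' in years to the next wave).
#'
#' @param records data.frame with columns `person_id`, `wave` (integer),
#'   `midpoint_year`, `sex`, `age`, `drinks_per_week`.
#' @param policy a [cutoff_policy()].
#' @return data.frame of class `state_panel` with an added `state` column
#'   and attributes `waves` (wave metadata) and `policy`.
#' @export
state_panel <- function(records, policy = cutoff_policy()) {
  need <- c("person_id", "wave", "midpoint_year", "sex", "age", "drinks_per_week")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, need]
  records$person_id <- as.character(records$person_id)
  records$wave <- as.integer(records$wave)
  if (anyDuplicated(records[, c("person_id", "wave")]))
    stop("(person_id, wave) pairs must be unique")
  if (any(records$age < 0, na.rm = TRUE)) stop("age must be non-negative")
  records$state <- classify_state(records$drinks_per_week, records$sex, policy)

  mids <- tapply(records$midpoint_year, records$wave, function(y) unique(y)[1])
  if (any(tapply(records$midpoint_year, records$wave,
                 function(y) length(unique(y))) > 1))
    stop("midpoint_year must be constant within a wave")
  waves <- data.frame(wave = as.integer(names(mids)),
                      midpoint_year = as.numeric(mids))
  waves <- waves[order(waves$wave), ]
  rownames(waves) <- NULL
  dt <- diff(waves$midpoint_year)
  if (length(dt) && any(dt <= 0))
    stop("wave midpoints must be strictly increasing")
  waves$interval_years <- c(dt, NA_real_)

  structure(records, waves = waves, policy = policy,
            class = c("state_panel", "data.frame"))
}

#' @export
print.state_panel <- function(x, ...) {
  w <- attr(x, "waves")
  cat(sprintf("State panel: %d records, %d persons, %d waves (%s-%s)\n",
              nrow(x), length(unique(x$person_id)), nrow(w),
              min(w$midpoint_year), max(w$midpoint_year)))
  tab <- table(factor(x$state, AMHA_STATES), useNA = "ifany")
  cat("States: ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Wave metadata of a panel
#'
#' @param panel a [state_panel()].
#' @return data.frame with `wave`, `midpoint_year`, `interval_years`.
#' @export
panel_waves <- function(panel) attr(panel, "waves")

#' Build an undirected social network
#'
#' Edges are undirected and deduplicated; self-loops are an error. An
#' optional `relation` label per edge (family, spouse, friend, coworker,
#' neighbour, other) drives the study filters.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `relation`.
#' @param nodes optional character vector of node ids (to keep isolates).
#' @return an `igraph` undirected simple graph with vertex `name` and edge
#'   `relation` attributes.
#' @export
social_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target") %in% names(edges)))
  src <- as.character(edges$source)
  dst <- as.character(edges$target)
  if (any(src == dst)) stop("self-loops are not allowed")
  rel <- if ("relation" %in% names(edges)) as.character(edges$relation)
         else rep("other", length(src))
  # canonical order so duplicates in either direction collapse
  a <- pmin(src, dst); b <- pmax(src, dst)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  verts <- unique(c(a, b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], relation = rel[keep],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = verts))
  g
}

#' Edge list of a social network
#'
#' @param network an igraph network from [social_network()].
#' @return data.frame with `source`, `target`, `relation`.
#' @export
network_edges <- function(network) {
  el <- igraph::as_data_frame(network, what = "edges")
  rel <- if ("relation" %in% names(el)) el$relation else rep("other", nrow(el))
  data.frame(source = el$from, target = el$to, relation = rel,
             stringsAsFactors = FALSE)
}

#' Apply the study's inclusion filters
#'
#' Restricts the panel to persons older than 21 with known drinking state,
#' removes coworker and neighbour edges (relationship types shown not to
#' carry drinking influence), and drops network vertices for persons no
#' longer in the panel (their incident edges go with them). Counts of
#' removed records, nodes and edges are attached as a `filter_log`
#' attribute on each returned object.
#'
#' @param panel a [state_panel()].
#' @param network an igraph network.
#' @param age_min exclusive lower age bound (default 21).
#' @param excluded_relations edge relation labels to drop.
#' @return list with filtered `panel` and `network`.
#' @export
apply_study_filters <- function(panel, network, age_min = 21,
                                excluded_relations = c("coworker", "neighbour")) {
  stopifnot(inherits(panel, "state_panel"))
  keep <- !is.na(panel$state) & !is.na(panel$age) & panel$age > age_min
  removed_records <- sum(!keep)
  fpanel <- panel[keep, , drop = FALSE]
  if (nrow(fpanel) == 0)
    stop("age/state filter removed every panel record (age > ", age_min,
         " with known drinking state)")
  fpanel <- state_panel(fpanel[, setdiff(names(fpanel), "state")],
                        attr(panel, "policy"))

  rel <- igraph::edge_attr(network, "relation")
  if (is.null(rel)) rel <- rep("other", igraph::ecount(network))
  drop_edges <- which(rel %in% excluded_relations)
  g <- igraph::delete_edges(network, drop_edges)
  persons <- unique(fpanel$person_id)
  drop_nodes <- setdiff(igraph::V(g)$name, persons)
  g <- igraph::delete_vertices(g, drop_nodes)
  if (igraph::vcount(g) == 0)
    stop("panel restriction removed every network node")

  log <- list(age_min = age_min,
              excluded_relations = excluded_relations,
              removed_panel_records = removed_records,
              removed_relation_edges = length(drop_edges),
              removed_nodes = length(drop_nodes),
              removed_incident_edges =
                igraph::ecount(network) - length(drop_edges) - igraph::ecount(g))
  attr(fpanel, "filter_log") <- log
  g <- igraph::set_graph_attr(g, "filter_log", log)
  list(panel = fpanel, network = g)
}

#' Extract wave-to-wave state transitions with neighbour context
#'
#' One record per person per consecutive wave pair where the state is
#' observed at both waves. The neighbour context (counts of network
#' neighbours in each state) is computed at the origin wave; neighbours
#' with unknown state are excluded from the counts, and persons absent from
#' the network contribute zero counts. Persons missing either wave are
#' silently skipped; the skip count is attached as attribute `n_skipped`.
#'
#' @param panel a [state_panel()] (at least two waves).
#' @param network an igraph network over (a subset of) the panel's persons.
#' @return data.frame of class `amha_transitions` with columns `person_id`,
#'   `wave`, `wave_next`, `from_state`, `to_state`, `n_A`, `n_M`, `n_H`,
#'   `interval_years`.
#' @export
extract_transitions <- function(panel, network) {
  stopifnot(inherits(panel, "state_panel"))
  waves <- panel_waves(panel)
  if (nrow(waves) < 2) stop("need at least two waves to extract transitions")

  persons <- sort(unique(panel$person_id))
  wmap <- match(panel$wave, waves$wave)
  pmap <- match(panel$person_id, persons)
  S <- matrix(NA_character_, length(persons), nrow(waves),
              dimnames = list(persons, NULL))
  S[cbind(pmap, wmap)] <- panel$state

  vnames <- igraph::V(network)$name
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  vrow <- match(vnames, persons)   # some vertices may lack panel records

  out <- vector("list", nrow(waves) - 1)
  n_skipped <- 0L
  for (wi in seq_len(nrow(waves) - 1)) {
    from <- S[, wi]; to <- S[, wi + 1]
    both <- !is.na(from) & !is.na(to)
    n_skipped <- n_skipped + sum(xor(is.na(from), is.na(to)))
    if (!any(both)) next
    # neighbour state counts at origin wave over the network's vertices
    vstate <- rep(NA_character_, length(vnames))
    has <- !is.na(vrow)
    vstate[has] <- from[vrow[has]]
    ind <- vapply(AMHA_STATES,
                  function(s) as.numeric(!is.na(vstate) & vstate == s),
                  numeric(length(vnames)))
    counts <- as.matrix(adj %*% ind)
    rownames(counts) <- vnames
    idx <- which(both)
    crow <- match(persons[idx], vnames)
    cts <- matrix(0, length(idx), 3, dimnames = list(NULL, AMHA_STATES))
    inn <- !is.na(crow)
    cts[inn, ] <- counts[crow[inn], , drop = FALSE]
    out[[wi]] <- data.frame(
      person_id = persons[idx],
      wave = waves$wave[wi],
      wave_next = waves$wave[wi + 1],
      from_state = from[idx],
      to_state = to[idx],
      n_A = cts[, "A"], n_M = cts[, "M"], n_H = cts[, "H"],
      interval_years = waves$interval_years[wi],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(person_id = character(), wave = integer(),
                      wave_next = integer(), from_state = character(),
                      to_state = character(), n_A = numeric(), n_M = numeric(),
                      n_H = numeric(), interval_years = numeric())
  rownames(res) <- NULL
  structure(res, n_skipped = n_skipped,
            class = c("amha_transitions", "data.frame"))
}

#' @export
print.amha_transitions <- function(x, ...) {
  cat(sprintf("Transition records: %d (skipped person-wave pairs: %d)\n",
              nrow(x), attr(x, "n_skipped")))
  print(table(from = factor(x$from_state, AMHA_STATES),
              to = factor(x$to_state, AMHA_STATES)))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read / write a state panel as CSV
#'
#' The CSV holds the raw observation columns; the state column is re-derived
#' on read under `policy`. Writers also emit a `<path>.meta.json` sidecar
#' recording any applied filters and record counts.
#'
#' @param panel a [state_panel()].
#' @param path CSV file path.
#' @param policy a [cutoff_policy()] used on read.
#' @return `read_panel` returns a [state_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("person_id", "wave", "midpoint_year", "sex", "age", "drinks_per_week")
  write.csv(as.data.frame(panel)[, cols], path, row.names = FALSE)
  meta <- list(kind = "state_panel", n_records = nrow(panel),
               n_persons = length(unique(panel$person_id)),
               filters = attr(panel, "filter_log"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, policy = cutoff_policy()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  state_panel(df, policy)
}

#' Read / write a social network as an edge-list CSV
#'
#' Columns `source`, `target`, `relation`. A `<path>.meta.json` sidecar
#' stores the full node list (so isolated vertices survive a round trip)
#' and any filter log.
#'
#' @param network an igraph network.
#' @param path CSV file path.
#' @return `read_network` returns an igraph network; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  write.csv(network_edges(network), path, row.names = FALSE)
  fl <- tryCatch(igraph::graph_attr(network, "filter_log"),
                 error = function(e) NULL)
  meta <- list(kind = "social_network", nodes = igraph::V(network)$name,
               n_edges = igraph::ecount(network), filters = fl)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  nodes <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    nodes <- meta$nodes
  }
  social_network(edges, nodes = nodes)
}
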