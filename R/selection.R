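# Cell selection: conjunctive filters, point-in-polygon geometry for
# box/lasso regions on embeddings, and manual group assignment.

#' Filter predicates and filter specifications
#'
#' A `filter_spec` is a conjunction of predicates, each selecting cells by a
#' categorical column (`filter_categorical`), an inclusive numeric range
#' (`filter_range`) or a region on a 2-D embedding (`filter_region`, either
#' a polygon with at least 3 vertices or an axis-aligned box). A cell passes
#' the filter iff it satisfies every predicate; the empty specification
#' selects all cells.
#'
#' @param ... For `filter_spec()`: predicate objects.
#' @param column Cell-table column name.
#' @param levels Character vector of allowed levels.
#' @param low,high Inclusive range bounds; `NULL` means unbounded.
#' @param embedding Embedding name.
#' @param polygon Matrix or list of >= 3 (x, y) vertices, implicitly closed.
#' @param box Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return A `filter_spec` or a single predicate object.
#' @seealso [apply_filter()], [filter_spec_to_json()]
#' @export
filter_spec <- function(...) {
  predicates <- list(...)
  if (length(predicates) == 1L && is.list(predicates[[1]]) &&
      !inherits(predicates[[1]], "filter_predicate")) {
    predicates <- predicates[[1]]
  }
  for (p in predicates) {
    if (!inherits(p, "filter_predicate")) {
      cd_stop("celldeck_spec_error",
              "filter_spec accepts only filter predicates")
    }
  }
  structure(list(predicates = predicates), class = "filter_spec")
}

#' @rdname filter_spec
#' @export
filter_categorical <- function(column, levels) {
  stopifnot(is_string(column))
  structure(list(type = "categorical", column = column,
                 levels = as.character(levels)),
            class = c("filter_categorical", "filter_predicate"))
}

#' @rdname filter_spec
#' @export
filter_range <- function(column, low = NULL, high = NULL) {
  stopifnot(is_string(column))
  structure(list(type = "range", column = column,
                 low = if (is.null(low)) -Inf else as.numeric(low),
                 high = if (is.null(high)) Inf else as.numeric(high)),
            class = c("filter_range", "filter_predicate"))
}

#' @rdname filter_spec
#' @export
filter_region <- function(embedding, polygon = NULL, box = NULL) {
  stopifnot(is_string(embedding))
  if (is.null(polygon) == is.null(box)) {
    cd_stop("celldeck_spec_error",
            "filter_region needs exactly one of polygon or box")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 4L || box[1] > box[2] || box[3] > box[4]) {
      cd_stop("celldeck_spec_error",
              "box must be c(xmin, xmax, ymin, ymax) with xmin <= xmax, ymin <= ymax")
    }
  } else {
    polygon <- as_polygon_matrix(polygon)
  }
  structure(list(type = "region", embedding = embedding, polygon = polygon,
                 box = box),
            class = c("filter_region", "filter_predicate"))
}

as_polygon_matrix <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon)) {
    polygon <- do.call(rbind, lapply(polygon, function(v) as.numeric(v)))
  }
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    cd_stop("celldeck_spec_error",
            "polygon needs >= 3 two-dimensional vertices")
  }
  polygon
}

#' Apply a filter specification to a dataset
#'
#' Returns exactly the cells satisfying all predicates (conjunction).
#' Referencing an unknown column or embedding is an error; an unknown level
#' inside an existing categorical column matches nothing and records a
#' warning.
#'
#' @param ds A `cell_dataset`.
#' @param spec A `filter_spec`.
#' @return Sorted integer vector of 1-based cell indices.
#' @export
apply_filter <- function(ds, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  keep <- rep(TRUE, n_cells(ds))
  for (p in spec$predicates) {
    keep <- keep & evaluate_predicate(ds, p)
  }
  which(keep)
}

evaluate_predicate <- function(ds, p) {
  if (p$type %in% c("categorical", "range")) {
    if (!p$column %in% names(ds$cell_table)) {
      cd_stop("celldeck_spec_error", "unknown cell column: %s", p$column)
    }
    v <- ds$cell_table[[p$column]]
  }
  switch(p$type,
    categorical = {
      present <- if (is.factor(v)) levels(v) else unique(as.character(v))
      unknown <- setdiff(p$levels, present)
      if (length(unknown)) {
        cd_warn("filter on '%s': level(s) %s not present, match nothing",
                p$column, paste(unknown, collapse = ", "))
      }
      as.character(v) %in% p$levels
    },
    range = {
      if (!is.numeric(v)) {
        cd_stop("celldeck_spec_error",
                "range filter on non-numeric column: %s", p$column)
      }
      !is.na(v) & v >= p$low & v <= p$high
    },
    region = {
      idx <- region_to_cells(ds, p$embedding,
                             if (is.null(p$box)) p$polygon else p$box,
                             kind = if (is.null(p$box)) "polygon" else "box")
      seq_len(n_cells(ds)) %in% idx
    },
    cd_stop("celldeck_spec_error", "unknown predicate type: %s", p$type)
  )
}

#' Point-in-polygon membership (boundary inclusive)
#'
#' Even-odd ray casting with an explicit boundary test: a point counts as
#' inside when it lies strictly inside or on an edge of the implicitly
#' closed polygon. Agrees with a winding-number formulation on
#' non-self-intersecting polygons.
#'
#' @param points n x 2 matrix (or coercible) of coordinates.
#' @param polygon m x 2 matrix of vertices, m >= 3, implicitly closed.
#' @return Logical vector of length n.
#' @export
points_in_polygon <- function(points, polygon) {
  polygon <- as_polygon_matrix(polygon)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) {
    cd_stop("celldeck_spec_error", "points must have 2 columns")
  }
  px <- points[, 1]; py <- points[, 2]
  vx <- polygon[, 1]; vy <- polygon[, 2]
  m <- nrow(polygon)
  nxt <- c(seq_len(m)[-1], 1L)
  inside <- rep(FALSE, nrow(points))
  boundary <- rep(FALSE, nrow(points))
  eps <- 1e-12 * max(1, max(abs(polygon)))
  for (i in seq_len(m)) {
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[nxt[i]]; y2 <- vy[nxt[i]]
    # on-segment test: zero cross product and inside the bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) <= eps &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on_seg
    # even-odd rule: horizontal ray to +x, half-open edge in y
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | boundary
}

#' Cells inside a region of an embedding
#'
#' A box is treated as its 4-vertex polygon; membership is boundary
#' inclusive, matching the intuitive behavior of box/lasso selection on a
#' scatter plot.
#'
#' @param ds A `cell_dataset`.
#' @param embedding Embedding name.
#' @param region Polygon matrix or `c(xmin, xmax, ymin, ymax)` box.
#' @param kind `"polygon"`, `"box"`, or `"auto"` (box when length-4 numeric).
#' @return Sorted integer vector of 1-based cell indices.
#' @export
region_to_cells <- function(ds, embedding, region, kind = "auto") {
  if (!embedding %in% names(ds$embeddings)) {
    cd_stop("celldeck_spec_error", "unknown embedding: %s", embedding)
  }
  coords <- ds$embeddings[[embedding]]
  if (kind == "auto") {
    kind <- if (is.numeric(region) && is.null(dim(region)) &&
                length(region) == 4L) "box" else "polygon"
  }
  if (kind == "box") {
    box <- as.numeric(region)
    if (box[1] > box[2] || box[3] > box[4]) {
      cd_stop("celldeck_spec_error", "degenerate box: xmin > xmax or ymin > ymax")
    }
    keep <- coords[, 1] >= box[1] & coords[, 1] <= box[2] &
      coords[, 2] >= box[3] & coords[, 2] <= box[4]
    which(keep)
  } else {
    which(points_in_polygon(coords, region))
  }
}

#' Assemble manual selections into disjoint groups
#'
#' Cells present in more than one selection are removed from all groups (a
#' warning reports the overlap count) so that downstream differential
#' expression never depends on selection order. Empty groups are permitted
#' here; [differential_expression()] enforces minimum group sizes.
#'
#' @param selections Named list: group label -> integer vector of cell
#'   indices.
#' @return A `group_assignment`: named list of sorted, disjoint index
#'   vectors.
#' @export
assign_groups <- function(selections) {
  if (is.null(names(selections)) || any(!nzchar(names(selections)))) {
    cd_stop("celldeck_spec_error", "all selections must be named")
  }
  sets <- lapply(selections, function(s) sort(unique(as.integer(s))))
  all_idx <- unlist(sets, use.names = FALSE)
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup)) {
    cd_warn("%d overlapping cell(s) removed from all groups", length(dup))
    sets <- lapply(sets, function(s) setdiff(s, dup))
  }
  structure(sets, class = "group_assignment", overlap = length(dup))
}

# JSON (de)serialization of filter specs, used by the web service ----------

#' Serialize / parse the JSON form of a filter specification
#'
#' The JSON form is an array of objects: `{"type":"categorical","column":
#' ...,"levels":[...]}`, `{"type":"range","column":...,"low":...,"high":
#' ...}` (omit a bound for an open range), and `{"type":"region",
#' "embedding":...,"polygon":[[x,y],...]}` or `..., "box":{"xmin":..,
#' "xmax":..,"ymin":..,"ymax":..}`.
#'
#' @param spec A `filter_spec`.
#' @return `filter_spec_to_json()`: a JSON string;
#'   `filter_spec_from_json()`: a `filter_spec`.
#' @export
filter_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  items <- lapply(spec$predicates, function(p) {
    switch(p$type,
      categorical = list(type = "categorical", column = p$column,
                         levels = I(p$levels)),
      range = {
        out <- list(type = "range", column = p$column)
        if (is.finite(p$low)) out$low <- p$low
        if (is.finite(p$high)) out$high <- p$high
        out
      },
      region = {
        out <- list(type = "region", embedding = p$embedding)
        if (!is.null(p$box)) {
          out$box <- list(xmin = p$box[1], xmax = p$box[2],
                          ymin = p$box[3], ymax = p$box[4])
        } else {
          out$polygon <- unname(lapply(seq_len(nrow(p$polygon)),
                                       function(i) p$polygon[i, ]))
        }
        out
      })
  })
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, digits = NA))
}

#' @rdname filter_spec_to_json
#' @param json JSON text as produced by `filter_spec_to_json()`.
#' @export
filter_spec_from_json <- function(json) {
  items <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  predicates <- lapply(items, function(it) {
    switch(as.character(it$type),
      categorical = filter_categorical(it$column,
                                       unlist(it$levels, use.names = FALSE)),
      range = filter_range(it$column, low = it$low, high = it$high),
      region = {
        if (!is.null(it$box)) {
          filter_region(it$embedding,
                        box = c(it$box$xmin, it$box$xmax, it$box$ymin,
                                it$box$ymax))
        } else {
          filter_region(it$embedding,
                        polygon = do.call(rbind, lapply(it$polygon,
                                                        unlist)))
        }
      },
      cd_stop("celldeck_spec_error", "unknown filter type in JSON: %s",
              it$type))
  })
  filter_spec(predicates)
}
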