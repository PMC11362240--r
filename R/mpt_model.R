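#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm qnorm rnorm runif rgamma rbeta dnorm dbeta rbinom
#'   rmultinom median quantile sd var cov integrate optim rWishart setNames
#'   dgamma rchisq aggregate density
NULL

# ---------------------------------------------------------------------------
# MPT model representation
#
# An mpt_model is a list with
#   parameters: character vector of free parameter names (order fixed)
#   derived:    named list of R expressions over free parameters
#   trees:      list of trees; each tree is list(name, categories, branches)
#               where branches is a list of branch records
#               list(category, factors) and each factor is
#               list(kind = "param" | "const", name, complement, value)
# Category probabilities are sums over branch products; every factor is
# either p, (1 - p) or a numeric constant in [0, 1].
# ---------------------------------------------------------------------------

new_mpt_model <- function(parameters, trees, derived = list()) {
  structure(
    list(parameters = parameters, trees = trees, derived = derived),
    class = "mpt_model"
  )
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("<mpt_model>\n")
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  if (length(x$derived)) {
    cat("  derived:   ",
        paste(vapply(names(x$derived), function(nm) {
          paste0(nm, " = ", deparse(x$derived[[nm]]))
        }, character(1)), collapse = "; "), "\n")
  }
  for (tr in x$trees) {
    cat("  tree ", tr$name, ": categories ",
        paste(tr$categories, collapse = ", "),
        " (", length(tr$branches), " branches)\n", sep = "")
  }
  invisible(x)
}

#' List the parameters of an MPT model
#'
#' @param model An `mpt_model`.
#' @return A tibble with columns `parameter` and `role` (`"free"` or
#'   `"derived"`).
#' @export
mpt_parameters <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  tibble(
    parameter = c(model$parameters, names(model$derived)),
    role = c(rep("free", length(model$parameters)),
             rep("derived", length(model$derived)))
  )
}

# --- branch-term parsing ----------------------------------------------------

# Decompose an R expression into multiplicative factors; each factor must be
# a number in [0,1], a bare name, or (1 - name). Returns a list of factor
# records or signals a condition with class "ordtree_parse_error".
parse_branch_term <- function(expr, line = NA_integer_) {
  bad <- function(what) {
    abort(
      paste0("unparseable branch term",
             if (!is.na(line)) paste0(" at line ", line),
             ": ", what),
      class = "ordtree_format_error"
    )
  }
  factors <- list()
  walk <- function(e) {
    if (is.call(e) && identical(e[[1]], as.name("*"))) {
      walk(e[[2]]); walk(e[[3]])
    } else if (is.call(e) && identical(e[[1]], as.name("("))) {
      walk_factor(e[[2]])
    } else {
      walk_factor(e)
    }
  }
  walk_factor <- function(e) {
    if (is.call(e) && identical(e[[1]], as.name("("))) {
      walk_factor(e[[2]])
    } else if (is.numeric(e)) {
      if (e < 0 || e > 1) bad(paste0("constant ", e, " outside [0, 1]"))
      factors[[length(factors) + 1L]] <<-
        list(kind = "const", name = NA_character_, complement = FALSE,
             value = as.numeric(e))
    } else if (is.name(e)) {
      factors[[length(factors) + 1L]] <<-
        list(kind = "param", name = as.character(e), complement = FALSE,
             value = NA_real_)
    } else if (is.call(e) && identical(e[[1]], as.name("-")) &&
               length(e) == 3L && is.numeric(e[[2]]) && e[[2]] == 1 &&
               is.name(e[[3]])) {
      factors[[length(factors) + 1L]] <<-
        list(kind = "param", name = as.character(e[[3]]), complement = TRUE,
             value = NA_real_)
    } else {
      bad(paste0("factor '", deparse(e), "' is not p, (1-p) or a constant"))
    }
  }
  walk(expr)
  if (!length(factors)) bad("empty term")
  factors
}

deparse_branch_term <- function(factors) {
  paste(vapply(factors, function(f) {
    if (f$kind == "const") format(f$value, digits = 15)
    else if (f$complement) paste0("(1-", f$name, ")")
    else f$name
  }, character(1)), collapse = "*")
}

# --- EQN input/output -------------------------------------------------------

#' Parse an MPT model from EQN text
#'
#' Reads the community-standard EQN interchange format: one branch per line,
#' `tree category branch-term`, whitespace-delimited.  An optional leading
#' line holding a single integer (the traditional branch count) is accepted
#' and ignored, as are blank lines and `#` comments.  Labels are
#' case-sensitive.
#'
#' @param text A character scalar holding EQN text, or a character vector of
#'   lines.
#' @param derived Optional named list of derived-parameter expressions
#'   (strings or calls), e.g. `list(D_New = "(D_A + D_B)/2")`.  Derived names
#'   may be referenced by branch terms.
#' @param validate If `TRUE` (default), check that every tree's category
#'   probabilities sum to one at randomly drawn parameter points.
#' @return An `mpt_model`.
#' @examples
#' m <- parse_eqn("T x p\nT y (1-p)")
#' mpt_parameters(m)
#' @export
parse_eqn <- function(text, derived = list(), validate = TRUE) {
  if (length(text) == 1L && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  raw <- lines
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) abort("no content in EQN input", class = "ordtree_format_error")
  # optional count header: first non-blank line containing a single integer
  first <- trimws(lines[keep[1]])
  if (grepl("^[0-9]+$", first)) keep <- keep[-1]
  rows <- list()
  for (ln in keep) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 3L) {
      abort(paste0("expected 'tree category term' at line ", ln, ": '",
                   trimws(raw[ln]), "'"), class = "ordtree_format_error")
    }
    term_txt <- paste(toks[-(1:2)], collapse = "")
    expr <- tryCatch(str2lang(term_txt), error = function(e) {
      abort(paste0("unparseable branch term at line ", ln, ": '", term_txt, "'"),
            class = "ordtree_format_error")
    })
    rows[[length(rows) + 1L]] <- list(
      tree = toks[1], category = toks[2],
      factors = parse_branch_term(expr, line = ln)
    )
  }
  derived <- normalize_derived(derived)
  build_model_from_rows(rows, derived, validate = validate)
}

#' Read an MPT model from an EQN file
#'
#' @param path Path to an EQN file.
#' @inheritParams parse_eqn
#' @return An `mpt_model`.
#' @export
read_eqn <- function(path, derived = list(), validate = TRUE) {
  parse_eqn(readLines(path, warn = FALSE), derived = derived,
            validate = validate)
}

normalize_derived <- function(derived) {
  if (!length(derived)) return(list())
  out <- lapply(derived, function(d) if (is.character(d)) str2lang(d) else d)
  stopifnot(!is.null(names(out)), all(nzchar(names(out))))
  out
}

build_model_from_rows <- function(rows, derived, validate = TRUE) {
  tree_names <- unique(vapply(rows, `[[`, character(1), "tree"))
  used <- unique(unlist(lapply(rows, function(r) {
    vapply(Filter(function(f) f$kind == "param", r$factors),
           `[[`, character(1), "name")
  })))
  derived_names <- names(derived)
  free <- setdiff(used, derived_names)
  # derived expressions may only reference free parameters
  for (nm in derived_names) {
    refs <- all.vars(derived[[nm]])
    extra <- setdiff(refs, c(free, used))
    free <- union(free, setdiff(refs, derived_names))
    if (any(refs %in% derived_names)) {
      abort(paste0("derived parameter '", nm,
                   "' may not reference other derived parameters"))
    }
  }
  free <- sort(unique(free))
  trees <- lapply(tree_names, function(tn) {
    br <- Filter(function(r) identical(r$tree, tn), rows)
    cats <- unique(vapply(br, `[[`, character(1), "category"))
    list(
      name = tn,
      categories = cats,
      branches = lapply(br, function(r) list(category = r$category,
                                             factors = r$factors))
    )
  })
  model <- new_mpt_model(free, trees, derived)
  if (validate) validate_mpt_model(model)
  model
}

#' Serialize an MPT model to EQN text
#'
#' @param model An `mpt_model`.
#' @param path Optional file path; when given the text is written there.
#' @param header If `TRUE`, prepend the traditional branch-count line.
#' @return The EQN text, invisibly when `path` is given.
#' @export
write_eqn <- function(model, path = NULL, header = FALSE) {
  stopifnot(inherits(model, "mpt_model"))
  lines <- character(0)
  for (tr in model$trees) {
    for (br in tr$branches) {
      lines <- c(lines, paste(tr$name, br$category,
                              deparse_branch_term(br$factors)))
    }
  }
  if (header) lines <- c(as.character(length(lines)), lines)
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

# --- validation -------------------------------------------------------------

# Deterministic quasi-random points in (0,1): Halton-style radical inverse,
# so validation does not touch the global RNG stream.
halton_matrix <- function(n, k) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
  stopifnot(k <= length(primes))
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  m <- vapply(seq_len(k), function(j) {
    vapply(seq_len(n), radical_inverse, numeric(1), base = primes[j])
  }, numeric(n))
  matrix(pmin(pmax(m, 1e-6), 1 - 1e-6), nrow = n)
}

#' Validate an MPT model's tree structure
#'
#' Checks that every tree's category probabilities sum to one at `n_points`
#' quasi-random parameter points (tolerance `tol`), that category labels are
#' unique within trees, and that every category has at least one branch.
#'
#' @param model An `mpt_model`.
#' @param n_points Number of parameter points.
#' @param tol Absolute tolerance on the branch sum.
#' @return The model, invisibly; signals a structural-validation error
#'   otherwise.
#' @export
validate_mpt_model <- function(model, n_points = 100, tol = 1e-9) {
  for (tr in model$trees) {
    if (anyDuplicated(tr$categories)) {
      abort(paste0("duplicate category labels in tree '", tr$name, "'"),
            class = "ordtree_structure_error")
    }
    cats_with_branch <- unique(vapply(tr$branches, `[[`, character(1),
                                      "category"))
    if (!setequal(cats_with_branch, tr$categories)) {
      abort(paste0("tree '", tr$name, "' has categories without branches"),
            class = "ordtree_structure_error")
    }
  }
  k <- max(1L, length(model$parameters))
  th <- halton_matrix(n_points, k)
  colnames(th) <- if (length(model$parameters)) model$parameters else "p"
  probs <- compute_tree_probs(model, th[, model$parameters, drop = FALSE])
  for (i in seq_along(model$trees)) {
    sums <- rowSums(probs[[i]])
    if (any(abs(sums - 1) > tol)) {
      abort(paste0("branch probabilities in tree '", model$trees[[i]]$name,
                   "' do not sum to 1 (max deviation ",
                   format(max(abs(sums - 1)), digits = 3), ")"),
            class = "ordtree_structure_error")
    }
  }
  invisible(model)
}

# --- evaluation -------------------------------------------------------------

# Evaluate derived parameters and return the full theta matrix
# (free + derived columns).
full_theta <- function(model, theta) {
  if (!length(model$derived)) return(theta)
  env <- new.env(parent = baseenv())
  for (nm in colnames(theta)) assign(nm, theta[, nm], envir = env)
  extra <- vapply(model$derived, function(e) eval(e, env),
                  numeric(nrow(theta)))
  if (nrow(theta) == 1L) extra <- matrix(extra, nrow = 1L,
                                         dimnames = list(NULL, names(model$derived)))
  cbind(theta, extra)
}

# theta: numeric matrix (n x free parameters), named columns.
# Returns list of n x categories probability matrices, one per tree (or per
# tree in tree_idx).
compute_tree_probs <- function(model, theta, tree_idx = NULL) {
  if (is.null(dim(theta))) {
    theta <- matrix(theta, nrow = 1, dimnames = list(NULL, names(theta)))
  }
  missing <- setdiff(model$parameters, colnames(theta))
  if (length(missing)) {
    abort(paste0("missing parameter value(s): ", paste(missing, collapse = ", ")),
          class = "ordtree_value_error")
  }
  th <- full_theta(model, theta[, model$parameters, drop = FALSE])
  n <- nrow(th)
  lapply(model$trees[tree_idx %||% seq_along(model$trees)], function(tr) {
    out <- matrix(0, n, length(tr$categories),
                  dimnames = list(NULL, tr$categories))
    for (br in tr$branches) {
      v <- rep(1, n)
      for (f in br$factors) {
        v <- v * if (f$kind == "const") f$value
                 else if (f$complement) 1 - th[, f$name]
                 else th[, f$name]
      }
      out[, br$category] <- out[, br$category] + v
    }
    out
  })
}

#' Category probabilities of an MPT model
#'
#' Evaluates each tree's category probabilities at one or more parameter
#' assignments.
#'
#' @param model An `mpt_model`.
#' @param theta A named numeric vector (one assignment), or a data frame /
#'   matrix with one column per free parameter (one assignment per row).
#' @return A tibble with columns `.row`, `tree`, `category`, `prob`.
#' @examples
#' m <- build_2htsm()
#' category_probabilities(m, c(D = 0.5, d = 0.5, b = 0.5, g = 0.5))
#' @export
category_probabilities <- function(model, theta) {
  stopifnot(inherits(model, "mpt_model"))
  if (is.data.frame(theta)) theta <- as.matrix(theta)
  probs <- compute_tree_probs(model, theta)
  n <- nrow(probs[[1]])
  out <- purrr::map2_dfr(probs, model$trees, function(p, tr) {
    tibble(
      .row = rep(seq_len(n), times = length(tr$categories)),
      tree = tr$name,
      category = rep(tr$categories, each = n),
      prob = as.vector(p)
    )
  })
  dplyr::arrange(out, .data$.row, factor(.data$tree,
                                         levels = vapply(model$trees, `[[`,
                                                         character(1), "name")))
}

# --- 2HTSM constructors -----------------------------------------------------

#' The two-high-threshold source-monitoring model (2HTSM)
#'
#' Builds the most parsimonious 2HTSM variant ("submodel 4"): item memory `D`
#' shared across sources and new items, a single source-memory parameter `d`,
#' item guessing `b`, and source guessing `g` (the probability of guessing
#' "source A").  Three trees: items from source A, items from source B, and
#' new items; response categories `A`, `B`, `New` in each.
#'
#' @return An `mpt_model` with free parameters `D`, `d`, `b`, `g`.
#' @export
build_2htsm <- function() {
  txt <- c(
    "sourceA A D*d + D*(1-d)*g + (1-D)*b*g",
    "sourceA B D*(1-d)*(1-g) + (1-D)*b*(1-g)",
    "sourceA New (1-D)*(1-b)",
    "sourceB B D*d + D*(1-d)*(1-g) + (1-D)*b*(1-g)",
    "sourceB A D*(1-d)*g + (1-D)*b*g",
    "sourceB New (1-D)*(1-b)",
    "new A (1-D)*b*g",
    "new B (1-D)*b*(1-g)",
    "new New D + (1-D)*(1-b)"
  )
  # EQN proper holds one branch per line; expand the "+" shorthand here
  expand <- unlist(lapply(txt, function(line) {
    toks <- strsplit(line, "\\s+")[[1]]
    head2 <- toks[1:2]
    terms <- strsplit(paste(toks[-(1:2)], collapse = " "), "+", fixed = TRUE)[[1]]
    paste(head2[1], head2[2], trimws(terms))
  }))
  m <- parse_eqn(expand)
  m$parameters <- c("D", "d", "b", "g")  # canonical order
  m
}

#' The Bell-style 2HTSM variant with source-specific memory
#'
#' Builds the adapted 2HTSM in which item memory and source memory are
#' estimated separately per source (`D_A`, `D_B`, `d_A`, `d_B`) while
#' distractor detection for new items is fixed to the average item memory,
#' `D_New = (D_A + D_B)/2`.  With two within-subject conditions this yields
#' 12 free parameters: per condition `D_A`, `D_B`, `d_A`, `d_B`, `b`, `g`,
#' suffixed `_<condition>`.
#'
#' @param condition_labels Character vector of two distinct condition labels.
#' @return An `mpt_model` with `6 * length(condition_labels)` free parameters
#'   and a derived `D_New_<condition>` per condition.
#' @export
build_2htsm_bell <- function(condition_labels = c("pleasant", "disgusting")) {
  if (anyDuplicated(condition_labels)) {
    abort("condition labels must be distinct", class = "ordtree_value_error")
  }
  lines <- character(0)
  derived <- list()
  par_order <- character(0)
  for (cond in condition_labels) {
    s <- function(p) paste0(p, "_", cond)
    DN <- s("D_New")
    lines <- c(lines,
      paste0("sourceA_", cond, " A ", s("D_A"), "*", s("d_A")),
      paste0("sourceA_", cond, " A ", s("D_A"), "*(1-", s("d_A"), ")*", s("g")),
      paste0("sourceA_", cond, " A (1-", s("D_A"), ")*", s("b"), "*", s("g")),
      paste0("sourceA_", cond, " B ", s("D_A"), "*(1-", s("d_A"), ")*(1-", s("g"), ")"),
      paste0("sourceA_", cond, " B (1-", s("D_A"), ")*", s("b"), "*(1-", s("g"), ")"),
      paste0("sourceA_", cond, " New (1-", s("D_A"), ")*(1-", s("b"), ")"),
      paste0("sourceB_", cond, " B ", s("D_B"), "*", s("d_B")),
      paste0("sourceB_", cond, " B ", s("D_B"), "*(1-", s("d_B"), ")*(1-", s("g"), ")"),
      paste0("sourceB_", cond, " B (1-", s("D_B"), ")*", s("b"), "*(1-", s("g"), ")"),
      paste0("sourceB_", cond, " A ", s("D_B"), "*(1-", s("d_B"), ")*", s("g")),
      paste0("sourceB_", cond, " A (1-", s("D_B"), ")*", s("b"), "*", s("g")),
      paste0("sourceB_", cond, " New (1-", s("D_B"), ")*(1-", s("b"), ")"),
      paste0("new_", cond, " A (1-", DN, ")*", s("b"), "*", s("g")),
      paste0("new_", cond, " B (1-", DN, ")*", s("b"), "*(1-", s("g"), ")"),
      paste0("new_", cond, " New ", DN),
      paste0("new_", cond, " New (1-", DN, ")*(1-", s("b"), ")")
    )
    derived[[DN]] <- str2lang(paste0("(", s("D_A"), " + ", s("D_B"), ")/2"))
    par_order <- c(par_order, s(c("D_A", "D_B", "d_A", "d_B", "b", "g")))
  }
  m <- parse_eqn(lines, derived = derived)
  m$parameters <- par_order
  m
}

# Parameter roles used by the prior presets: memory-type (D, d) versus
# guessing-type (b, g).  Inferred from the leading letter of the name, the
# convention used by the built-in constructors; override via the `roles`
# argument of the preset functions.
default_parameter_roles <- function(model) {
  lead <- sub("^([A-Za-z]+).*$", "\\1", model$parameters)
  role <- ifelse(lead %in% c("D", "d"), "memory",
                 ifelse(lead %in% c("b", "g", "a"), "guessing", NA_character_))
  setNames(role, model$parameters)
}
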