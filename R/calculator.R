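#' @title Image calculator
#' @description A small, fixed expression language over individual images
#'   (`i1`, `i2`, ...) and image groups (`g1`, `g2`, ...): elementwise
#'   `+ - * /` (with `.*` and `./` accepted as synonyms), comparisons
#'   (`> < >= <=`, yielding 0/1 masks), parentheses, numeric literals, and
#'   the functions `mean(g)`, `std(g)` (n-1 denominator) and
#'   `corr(g1, g2, "temporal"|"spatial")`. Group-vs-group operations apply
#'   pairwise to corresponding images. This is deliberately not a
#'   general-purpose evaluator.
#' @name image-calculator
NULL

calc_tokenize <- function(text) {
  pats <- c(num = "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
            ident = "^[A-Za-z][A-Za-z0-9]*",
            str = '^"[^"]*"',
            ws = "^[[:space:]]+")
  toks <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    if (grepl(pats["ws"], rest)) {
      m <- regmatches(rest, regexpr(pats["ws"], rest))
    } else if (grepl(pats["num"], rest)) {
      m <- regmatches(rest, regexpr(pats["num"], rest))
      toks[[length(toks) + 1L]] <- list(type = "num", text = m, pos = pos)
    } else if (grepl(pats["ident"], rest)) {
      m <- regmatches(rest, regexpr(pats["ident"], rest))
      toks[[length(toks) + 1L]] <- list(type = "ident", text = m, pos = pos)
    } else if (grepl(pats["str"], rest)) {
      m <- regmatches(rest, regexpr(pats["str"], rest))
      toks[[length(toks) + 1L]] <- list(type = "str",
                                        text = gsub('"', "", m), pos = pos)
    } else {
      opm <- regexpr("^(\\.\\*|\\./|>=|<=|[-+*/><(),])", rest)
      if (opm == -1L)
        stop("calc parse error at position ", pos, ": unexpected '",
             substr(rest, 1, 1), "'")
      m <- regmatches(rest, opm)
      toks[[length(toks) + 1L]] <- list(type = "op", text = m, pos = pos)
    }
    pos <- pos + nchar(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  toks
}

#' Parse a calculator expression
#'
#' @param text expression text, e.g. `"(i1-mean(g1))./std(g1)"`.
#' @return an abstract syntax tree (class `CalcExpression`).
#' @export
calc_parse <- function(text) {
  if (!nzchar(trimws(text))) stop("calc parse error: empty expression")
  toks <- calc_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  state$len <- nchar(text)
  ast <- parse_cmp(state)
  if (state$i <= length(state$toks)) {
    t <- state$toks[[state$i]]
    stop("calc parse error at position ", t$pos, ": unexpected '", t$text, "'")
  }
  structure(ast, class = "CalcExpression")
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { t <- st$toks[[st$i]]; st$i <- st$i + 1L; t }
expect_op <- function(st, op) {
  t <- peek(st)
  if (is.null(t) || t$type != "op" || t$text != op)
    stop("calc parse error at position ",
         if (is.null(t)) st$len + 1L else t$pos,
         ": expected '", op, "'")
  advance(st)
}

parse_cmp <- function(st) {
  lhs <- parse_add(st)
  t <- peek(st)
  if (!is.null(t) && t$type == "op" && t$text %in% c(">", "<", ">=", "<=")) {
    advance(st)
    rhs <- parse_add(st)
    lhs <- list(type = "binop", op = t$text, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_add <- function(st) {
  lhs <- parse_mul(st)
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "op" || !t$text %in% c("+", "-")) break
    advance(st)
    lhs <- list(type = "binop", op = t$text, lhs = lhs, rhs = parse_mul(st))
  }
  lhs
}

parse_mul <- function(st) {
  lhs <- parse_unary(st)
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "op" ||
        !t$text %in% c("*", "/", ".*", "./")) break
    advance(st)
    op <- if (t$text %in% c("*", ".*")) "*" else "/"
    lhs <- list(type = "binop", op = op, lhs = lhs, rhs = parse_unary(st))
  }
  lhs
}

parse_unary <- function(st) {
  t <- peek(st)
  if (!is.null(t) && t$type == "op" && t$text == "-") {
    advance(st)
    return(list(type = "neg", x = parse_unary(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  t <- peek(st)
  if (is.null(t)) stop("calc parse error at position ", st$len + 1L,
                       ": unexpected end of expression")
  if (t$type == "num") { advance(st); return(list(type = "num",
                                                  value = as.numeric(t$text))) }
  if (t$type == "op" && t$text == "(") {
    advance(st)
    inner <- parse_cmp(st)
    expect_op(st, ")")
    return(inner)
  }
  if (t$type == "ident") {
    advance(st)
    name <- t$text
    if (name %in% c("mean", "std", "corr")) {
      expect_op(st, "(")
      args <- list(parse_cmp(st))
      while (!is.null(p <- peek(st)) && p$type == "op" && p$text == ",") {
        advance(st)
        p2 <- peek(st)
        if (!is.null(p2) && p2$type == "str") {
          advance(st)
          args[[length(args) + 1L]] <- list(type = "str", value = p2$text)
        } else {
          args[[length(args) + 1L]] <- parse_cmp(st)
        }
      }
      expect_op(st, ")")
      return(list(type = "call", fn = name, args = args))
    }
    if (grepl("^[ig][0-9]+$", name))
      return(list(type = "operand", name = name))
    stop("calc parse error at position ", t$pos, ": unknown identifier '",
         name, "'")
  }
  stop("calc parse error at position ", t$pos, ": unexpected '", t$text, "'")
}

#' Render a parsed expression back to text
#' @param ast a `CalcExpression`.
#' @return character scalar; `calc_parse(calc_unparse(ast))` is semantically
#'   identical to `ast`.
#' @export
calc_unparse <- function(ast) {
  rec <- function(n) switch(n$type,
    num = format(n$value),
    str = paste0('"', n$value, '"'),
    operand = n$name,
    neg = paste0("-", rec(n$x)),
    binop = paste0("(", rec(n$lhs), " ", n$op, " ", rec(n$rhs), ")"),
    call = paste0(n$fn, "(", paste(vapply(n$args, rec, ""), collapse = ", "),
                  ")"),
    stop("unknown node"))
  rec(ast)
}

# -- evaluation ---------------------------------------------------------

# internal value wrappers: scalar | image (array) | group (list of arrays)
cv_scalar <- function(v) list(kind = "scalar", v = v)
cv_image <- function(a) list(kind = "image", a = a)
cv_group <- function(l) list(kind = "group", l = l)

calc_bind <- function(bindings) {
  ref <- NULL
  vals <- list()
  for (nm in names(bindings)) {
    b <- bindings[[nm]]
    if (grepl("^i[0-9]+$", nm)) {
      a <- if (is.list(b)) b$data else b
      vals[[nm]] <- cv_image(a)
      if (is.null(ref) && is.list(b)) ref <- b$affine
    } else if (grepl("^g[0-9]+$", nm)) {
      l <- lapply(b, function(x) if (is.list(x)) x$data else x)
      vals[[nm]] <- cv_group(l)
      if (is.null(ref) && is.list(b[[1]])) ref <- b[[1]]$affine
    } else stop("calc: binding names must look like i1, g2, ...; got ", nm)
  }
  dims <- lapply(vals, function(v)
    if (v$kind == "image") dim(v$a) else dim(v$l[[1]]))
  sd <- dims[[1]]
  for (d in dims) if (length(d) != length(sd) || !all(d[1:3] == sd[1:3]))
    stop("calc: bound images are not on a common grid")
  list(vals = vals, affine = if (is.null(ref)) diag(4) else ref)
}

calc_binop <- function(op, a, b, qcenv) {
  f <- switch(op,
    "+" = `+`, "-" = `-`, "*" = `*`,
    "/" = function(x, y) {
      bad <- y == 0
      qcenv$div_by_zero <- qcenv$div_by_zero + sum(bad)
      out <- x / y
      out[bad] <- 0
      out
    },
    ">" = function(x, y) (x > y) * 1.0, "<" = function(x, y) (x < y) * 1.0,
    ">=" = function(x, y) (x >= y) * 1.0, "<=" = function(x, y) (x <= y) * 1.0)
  ab <- paste(a$kind, b$kind)
  switch(ab,
    "scalar scalar" = cv_scalar(f(a$v, b$v)),
    "scalar image" = cv_image(array(f(a$v, b$a), dim = dim(b$a))),
    "image scalar" = cv_image(array(f(a$a, b$v), dim = dim(a$a))),
    "image image" = {
      if (!identical(dim(a$a), dim(b$a))) stop("calc: image shape mismatch")
      cv_image(array(f(a$a, b$a), dim = dim(a$a)))
    },
    "group scalar" = cv_group(lapply(a$l, function(x)
      array(f(x, b$v), dim = dim(x)))),
    "scalar group" = cv_group(lapply(b$l, function(x)
      array(f(a$v, x), dim = dim(x)))),
    "group image" = cv_group(lapply(a$l, function(x)
      array(f(x, b$a), dim = dim(x)))),
    "image group" = cv_group(lapply(b$l, function(x)
      array(f(a$a, x), dim = dim(x)))),
    "group group" = {
      if (length(a$l) != length(b$l))
        stop("calc: pairwise operation on groups of unequal sizes (",
             length(a$l), " vs ", length(b$l), ")")
      cv_group(mapply(function(x, y) array(f(x, y), dim = dim(x)),
                      a$l, b$l, SIMPLIFY = FALSE))
    },
    stop("calc: cannot combine ", a$kind, " and ", b$kind))
}

calc_eval_node <- function(node, vals, qcenv, mask = NULL) {
  switch(node$type,
    num = cv_scalar(node$value),
    operand = {
      v <- vals[[node$name]]
      if (is.null(v)) stop("calc: operand '", node$name, "' is not bound")
      v
    },
    neg = {
      x <- calc_eval_node(node$x, vals, qcenv, mask)
      calc_binop("-", cv_scalar(0), x, qcenv)
    },
    binop = calc_binop(node$op,
                       calc_eval_node(node$lhs, vals, qcenv, mask),
                       calc_eval_node(node$rhs, vals, qcenv, mask),
                       qcenv),
    call = calc_eval_call(node, vals, qcenv, mask),
    stop("calc: cannot evaluate node of type ", node$type))
}

calc_eval_call <- function(node, vals, qcenv, mask) {
  if (node$fn %in% c("mean", "std")) {
    if (length(node$args) != 1L) stop("calc: ", node$fn, "() takes one group")
    g <- calc_eval_node(node$args[[1]], vals, qcenv, mask)
    if (g$kind != "group") stop("calc: ", node$fn, "() needs a group operand")
    if (node$fn == "std" && length(g$l) > 1L && length(g$l) <= 100L)
      warning("calc: std() over a group of ", length(g$l),
              " images; z-scoring is only well calibrated for large groups",
              call. = FALSE)
    m <- do.call(cbind, lapply(g$l, as.vector))
    d <- dim(g$l[[1]])
    if (node$fn == "mean") return(cv_image(array(rowMeans(m), dim = d)))
    v <- sqrt(rowSums(sweep(m, 1L, rowMeans(m))^2) / (ncol(m) - 1L))
    return(cv_image(array(v, dim = d)))
  }
  if (node$fn == "corr") {
    if (length(node$args) != 3L || node$args[[3]]$type != "str")
      stop('calc: corr() needs (group, group, "temporal"|"spatial")')
    g1 <- calc_eval_node(node$args[[1]], vals, qcenv, mask)
    g2 <- calc_eval_node(node$args[[2]], vals, qcenv, mask)
    mode <- node$args[[3]]$value
    to_group <- function(g) switch(g$kind, group = g$l, image = list(g$a),
                                   stop("calc: corr() needs image operands"))
    res <- corr_group_arrays(to_group(g1), to_group(g2), mode, mask, qcenv)
    if (is.data.frame(res)) return(res)
    return(cv_image(res))
  }
  stop("calc: unknown function ", node$fn)
}

# correlation between two groups of arrays; mode temporal -> per-voxel map,
# mode spatial -> one r per pair over (in-mask) voxels
corr_group_arrays <- function(l1, l2, mode, mask, qcenv) {
  mode <- match.arg(mode, c("temporal", "spatial"))
  if (mode == "temporal") {
    # two 4D images: correlate across time; two groups of 3D: across subjects
    stack <- function(l) {
      if (length(l) == 1L && length(dim(l[[1]])) == 4L) {
        d <- dim(l[[1]])
        list(m = t(matrix(l[[1]], prod(d[1:3]), d[4])), shape = d[1:3])
      } else {
        list(m = do.call(rbind, lapply(l, as.vector)),
             shape = dim(l[[1]])[1:3])
      }
    }
    s1 <- stack(l1); s2 <- stack(l2)
    if (!identical(dim(s1$m), dim(s2$m)))
      stop("calc: corr(temporal) needs matching series lengths/group sizes")
    if (nrow(s1$m) < 3L)
      stop("calc: corr(temporal) needs at least 3 observations per voxel")
    a <- sweep(s1$m, 2L, colMeans(s1$m))
    b <- sweep(s2$m, 2L, colMeans(s2$m))
    den <- sqrt(colSums(a^2) * colSums(b^2))
    r <- numeric(ncol(a))
    ok <- den > 0
    r[ok] <- colSums(a[, ok, drop = FALSE] * b[, ok, drop = FALSE]) / den[ok]
    qcenv$zero_variance <- qcenv$zero_variance + sum(!ok)
    return(array(pmin(1, pmax(-1, r)), dim = s1$shape))
  }
  if (length(l1) != length(l2))
    stop("calc: corr(spatial) needs equal group sizes")
  sel <- if (is.null(mask)) NULL else as.vector(mask$data)
  rows <- lapply(seq_along(l1), function(k) {
    x <- as.vector(l1[[k]]); y <- as.vector(l2[[k]])
    if (!is.null(sel)) { x <- x[sel]; y <- y[sel] }
    flag <- stats::sd(x) == 0 || stats::sd(y) == 0
    data.frame(pair = k, r = if (flag) NA_real_ else stats::cor(x, y),
               n_voxels = length(x), degenerate = flag)
  })
  do.call(rbind, rows)
}

#' Evaluate a calculator expression over bound images
#'
#' @param expr expression text or a parsed `CalcExpression`.
#' @param bindings named list binding operands to images: `i<k>` to a
#'   `Volume3D`/`Volume4D` (or bare array), `g<k>` to a list of them.
#' @param mask optional `Mask`, used by `corr(..., "spatial")`.
#' @return a `Volume3D`/`Volume4D`, a list of volumes (group result), a
#'   scalar, or a data.frame (spatial correlation). QC counters (divisions
#'   by zero, zero-variance voxels) are attached as `attr(, "qc")`.
#' @export
calc_evaluate <- function(expr, bindings, mask = NULL) {
  ast <- if (inherits(expr, "CalcExpression")) expr else calc_parse(expr)
  bound <- calc_bind(bindings)
  qcenv <- new.env(parent = emptyenv())
  qcenv$div_by_zero <- 0L
  qcenv$zero_variance <- 0L
  res <- calc_eval_node(ast, bound$vals, qcenv, mask)
  qc <- list(div_by_zero = qcenv$div_by_zero,
             zero_variance = qcenv$zero_variance)
  wrap <- function(a) {
    if (length(dim(a)) == 3L) volume3d(a, bound$affine)
    else a
  }
  out <- if (is.data.frame(res)) res
  else switch(res$kind,
              scalar = res$v,
              image = wrap(res$a),
              group = lapply(res$l, wrap))
  attr(out, "qc") <- qc
  out
}

#' Temporal or spatial correlation between two image groups
#'
#' `mode = "temporal"`: per-voxel correlation either across time (two 4D
#' volumes) or across subjects (two equal-length groups of 3D maps), e.g.
#' ReHo vs ALFF across participants. `mode = "spatial"`: one correlation
#' per corresponding image pair, computed over (in-mask) voxels, returned
#' as a table.
#'
#' @param g1,g2 `Volume4D`, or lists of `Volume3D`.
#' @param mode `"temporal"` or `"spatial"`.
#' @param mask optional `Mask`.
#' @return a `Volume3D` r map (temporal) or a data.frame (spatial).
#' @export
corr_group <- function(g1, g2, mode = c("temporal", "spatial"), mask = NULL) {
  mode <- match.arg(mode)
  norm <- function(g) if (is.list(g) && !is.null(g$data)) list(g) else g
  g1 <- norm(g1); g2 <- norm(g2)
  aff <- g1[[1]]$affine
  qcenv <- new.env(parent = emptyenv())
  qcenv$zero_variance <- 0L
  res <- corr_group_arrays(lapply(g1, `[[`, "data"),
                           lapply(g2, `[[`, "data"), mode, mask, qcenv)
  if (is.data.frame(res)) return(res)
  out <- volume3d(res, aff)
  attr(out, "qc") <- list(zero_variance = qcenv$zero_variance)
  out
}
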