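#' Abridged age groups
#'
#' Build the age grid used throughout the package: contiguous closed groups of
#' a fixed width followed by one open-ended terminal group.  The default grid,
#' 60-64, 65-69, ..., 80-84, 85+, matches the ages at which health expectancy
#' is usually reported for older-adult surveys.
#'
#' @param from start age of the first group, in years.
#' @param open_from start age of the open terminal group.
#' @param width width of the closed groups, in years.
#' @return A data frame with columns `x` (interval start age) and `n`
#'   (interval width; `Inf` flags the open group).
#' @examples
#' age_groups()
#' age_groups(50, 90, 5)
#' @export
age_groups <- function(from = 60, open_from = 85, width = 5) {
  stopifnot(is.numeric(from), is.numeric(open_from), is.numeric(width),
            width > 0, open_from > from)
  if ((open_from - from) %% width != 0)
    stop("'open_from' must be reachable from 'from' in steps of 'width'")
  x <- seq(from, open_from, by = width)
  data.frame(x = x, n = c(rep(width, length(x) - 1L), Inf))
}

check_age_grid <- function(x, n) {
  if (length(x) == 0L) stop("empty age grid")
  if (length(x) != length(n)) stop("'x' and 'n' must have equal length")
  if (any(!is.finite(x))) stop("group start ages must be finite")
  if (!all(is.infinite(n[length(n)]))) stop("last age group must be open (n = Inf)")
  if (length(n) > 1L && any(is.infinite(n[-length(n)])))
    stop("only the last age group may be open")
  if (length(x) > 1L) {
    gap <- x[-1L] - (x[-length(x)] + n[-length(n)])
    if (any(abs(gap) > 1e-9))
      stop("age groups are not contiguous: each x must equal previous x + n")
  }
  invisible(TRUE)
}

#' Construct an abridged period life table from central death rates
#'
#' Builds the standard abridged life-table columns (qx, lx, dx, Lx, Tx, ex)
#' from age-group central death rates mx.  Closed groups use the conversion
#' \deqn{q_x = n m_x / (1 + (n - a_x) m_x)}
#' and person-years \eqn{L_x = n\,l_{x+n} + a_x d_x}; the open terminal group
#' is closed with \eqn{q_x = 1} and \eqn{L_x = l_x / m_x} (constant hazard).
#'
#' @param x interval start ages (years), contiguous.
#' @param n interval widths (years); the last entry must be `Inf` (open group).
#'   `x` and `n` may instead be given jointly as an [age_groups()] data frame
#'   passed to `x`, leaving `n` missing.
#' @param mx central death rates per person-year, one per group, all positive.
#' @param ax mean years lived in the interval by those dying in it.  Defaults
#'   to `n/2` for closed groups (adequate for adult ages); ignored for the
#'   open group, where it is implied by `1/mx`.
#' @param sex optional label ("woman"/"man" or any string) carried on the table.
#' @param radix starting cohort size l(x0); all derived quantities reported by
#'   the package are radix-invariant.
#' @return An object of class `lifetable`: a data frame with columns
#'   `x, n, mx, ax, qx, lx, dx, Lx, Tx, ex` and attributes `sex` and `radix`.
#' @examples
#' lt <- lifetable(age_groups(), mx = 0.01 * exp(0.09 * (seq(60, 85, 5) - 60)))
#' lt
#' life_expectancy(lt, 60)
#' @seealso [life_expectancy()], [truncate_lifetable()], [read_lifetable()]
#' @export
lifetable <- function(x, n, mx, ax = NULL, sex = NA_character_, radix = 1e5) {
  if (is.data.frame(x)) {
    if (!missing(n)) stop("give the age grid either as a data frame or as x and n, not both")
    n <- x$n
    x <- x$x
  }
  check_age_grid(x, n)
  k <- length(x)
  if (length(mx) != k) stop("'mx' must have one rate per age group")
  if (any(!is.finite(mx)) || any(mx <= 0)) stop("all 'mx' must be positive and finite")
  if (!is.numeric(radix) || length(radix) != 1L || radix <= 0)
    stop("'radix' must be a positive number")

  if (is.null(ax)) {
    ax <- n / 2
  } else {
    if (length(ax) == 1L) ax <- rep(ax, k)
    if (length(ax) != k) stop("'ax' must be scalar or one value per group")
  }
  closed <- is.finite(n)
  if (any(ax[closed] <= 0 | ax[closed] >= n[closed]))
    stop("closed-group 'ax' must lie strictly inside (0, n)")
  ax[!closed] <- 1 / mx[!closed]

  qx <- numeric(k)
  qx[closed] <- n[closed] * mx[closed] / (1 + (n[closed] - ax[closed]) * mx[closed])
  qx[!closed] <- 1
  if (any(qx[closed] <= 0 | qx[closed] > 1))
    stop("computed qx outside (0, 1] for a closed group; mx and ax are incompatible")

  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- numeric(k)
  if (k > 1L) {
    lnext <- c(lx[-1L], 0)
    Lx[closed] <- n[closed] * lnext[closed] + ax[closed] * dx[closed]
  }
  Lx[!closed] <- lx[!closed] / mx[!closed]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx

  out <- data.frame(x = x, n = n, mx = mx, ax = ax, qx = qx,
                    lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  structure(out, class = c("lifetable", "data.frame"),
            sex = sex, radix = radix)
}

#' Coerce a full life-table data frame to a `lifetable`
#'
#' Accepts a data frame that already carries `x, n, mx` (and optionally `ax`)
#' and rebuilds the derived columns through [lifetable()], so every invariant
#' is re-checked.
#'
#' @param df data frame with at least `x`, `n`, `mx`; optional `ax`.
#' @param sex,radix as in [lifetable()]; `sex` falls back to a `sex` column.
#' @return A `lifetable`.
#' @export
as_lifetable <- function(df, sex = NULL, radix = 1e5) {
  stopifnot(is.data.frame(df))
  need <- c("x", "n", "mx")
  if (!all(need %in% names(df)))
    stop("data frame must contain columns: ", paste(need, collapse = ", "))
  if (is.null(sex)) sex <- if ("sex" %in% names(df)) as.character(df$sex[1L]) else NA_character_
  lifetable(df$x, df$n, df$mx, ax = if ("ax" %in% names(df)) df$ax else NULL,
            sex = sex, radix = radix)
}

#' @export
print.lifetable <- function(x, digits = 5, ...) {
  sx <- attr(x, "sex")
  cat("Abridged life table",
      if (!is.na(sx)) paste0(" (", sx, ")"), "\n", sep = "")
  cat("  radix ", format(attr(x, "radix")),
      ", ages ", x$x[1L], "-", x$x[nrow(x)], "+\n", sep = "")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE, ...)
  invisible(x)
}

lt_row <- function(lt, age) {
  i <- which(abs(lt$x - age) < 1e-9)
  if (length(i) != 1L)
    stop("age ", age, " is not a group boundary of this life table")
  i
}

#' Remaining life expectancy at an exact age
#'
#' @param lt a [lifetable()].
#' @param age a group boundary present in the table.
#' @return Remaining life expectancy ex at `age`, in years.
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "lifetable"))
  lt$ex[lt_row(lt, age)]
}

#' Truncate a life table at an age boundary
#'
#' Drops all groups below `age` and rescales survivors so the first retained
#' row equals the radix.  Conditional quantities (qx, ex) at retained ages are
#' unchanged.
#'
#' @inheritParams life_expectancy
#' @return A `lifetable` starting at `age`.
#' @export
truncate_lifetable <- function(lt, age) {
  stopifnot(inherits(lt, "lifetable"))
  i <- seq(lt_row(lt, age), nrow(lt))
  lifetable(lt$x[i], lt$n[i], lt$mx[i], ax = lt$ax[i],
            sex = attr(lt, "sex"), radix = attr(lt, "radix"))
}

#' Read an abridged life table from CSV
#'
#' The CSV carries one row per age group with header
#' `sex,x,n,mx[,qx][,ax]`; exactly one of `mx` or `qx` must be present, the
#' open group is encoded `n = -1`, decimals use ".".  When the file carries
#' `qx`, closed-group rates are back-solved through
#' `mx = qx / (n - (n - ax) qx)`; the open group's rate is unrecoverable from
#' `qx = 1`, so the `qx` variant requires an `ax` column and uses
#' `mx = 1/ax` in the open group.
#'
#' @param path file path.
#' @param radix radix for the reconstructed table.
#' @return A `lifetable`.
#' @export
read_lifetable <- function(path, radix = 1e5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sex", "x", "n")
  if (!all(need %in% names(df)))
    stop("life-table CSV must contain columns: ", paste(need, collapse = ", "))
  has_mx <- "mx" %in% names(df)
  has_qx <- "qx" %in% names(df)
  if (has_mx == has_qx)
    stop("life-table CSV must contain exactly one of 'mx' or 'qx'")
  for (col in intersect(c("x", "n", "mx", "qx", "ax"), names(df)))
    if (!is.numeric(df[[col]]))
      stop("malformed non-numeric values in column '", col, "'")
  n <- ifelse(df$n < 0, Inf, df$n)
  ax <- if ("ax" %in% names(df)) df$ax else n / 2
  if (has_mx) {
    mx <- df$mx
  } else {
    if (!"ax" %in% names(df))
      stop("the qx schema requires an 'ax' column (open-group mx = 1/ax)")
    open <- !is.finite(n)
    qx <- df$qx
    if (any(qx[!open] <= 0 | qx[!open] >= 1))
      stop("closed-group qx must lie in (0, 1)")
    mx <- numeric(length(qx))
    mx[!open] <- qx[!open] / (n[!open] - (n[!open] - ax[!open]) * qx[!open])
    mx[open] <- 1 / ax[open]
  }
  lifetable(df$x, n, mx, ax = replace(ax, !is.finite(n), NA_real_),
            sex = as.character(df$sex[1L]), radix = radix)
}

#' Write an abridged life table to CSV
#'
#' Writes the schema accepted by [read_lifetable()] (`sex,x,n,mx,ax`; open
#' group encoded `n = -1`).
#'
#' @param lt a `lifetable`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  stopifnot(inherits(lt, "lifetable"))
  df <- data.frame(sex = attr(lt, "sex"), x = lt$x,
                   n = ifelse(is.finite(lt$n), lt$n, -1),
                   mx = lt$mx, ax = lt$ax)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
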