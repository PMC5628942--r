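## Boolean keyword query language used for disaster-specific tweet filtering.
##
## Grammar (informal):
##   * a space between operands denotes AND (adjacency);
##   * a standalone uppercase "OR" separates alternatives and binds looser
##     than adjacency;
##   * parentheses group clauses;
##   * quoted spans ('sandy hook' or "sandy hook") are exact consecutive-token
##     phrases;
##   * an OR alternative consisting of several unquoted words ("finish line",
##     "San Francisco") is treated as a phrase, not a conjunction: treating it
##     as AND would let "San Francisco" match texts mentioning San Diego and
##     Francisco Street.
## Matching is case-insensitive and token-based: text is lowercased and split
## into maximal runs of Unicode letters/digits, so "#PrayForBoston" yields the
## token "prayforboston" and '214' cannot match inside "62148".

#' Tokenize text for keyword matching
#'
#' Lowercases the input and splits it into maximal runs of Unicode letters and
#' digits; every other character is a separator. Hashtags and mentions
#' therefore yield their bare token (`"#sf"` -> `"sf"`).
#'
#' @param text A single character string.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Plane crash at SFO!")
#' tokenize("#PrayForBoston RT @cnn")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  tokenize_all(text)[[1L]]
}

## Vectorized tokenizer: character vector -> list of token vectors.
tokenize_all <- function(texts) {
  texts <- tolower(as.character(texts))
  texts[is.na(texts)] <- ""
  m <- gregexpr("[\\p{L}\\p{N}]+", texts, perl = TRUE)
  out <- regmatches(texts, m)
  lapply(out, function(x) if (length(x) == 1L && is.na(x[1L])) character(0) else x)
}

## ---- AST constructors -----------------------------------------------------

new_rule_node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "mce_rule")
}

rule_term <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  new_rule_node("term", token = token)
}

rule_phrase <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1L, all(nzchar(tokens)))
  new_rule_node("phrase", tokens = tokens)
}

rule_and <- function(children) {
  stopifnot(length(children) >= 2L)
  new_rule_node("and", children = children)
}

rule_or <- function(children) {
  stopifnot(length(children) >= 2L)
  new_rule_node("or", children = children)
}

#' @export
print.mce_rule <- function(x, ...) {
  cat("<filter rule> ", render_rule(x), "\n", sep = "")
  invisible(x)
}

## ---- Lexer ----------------------------------------------------------------

rule_lex <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  toks <- vector("list", 0L)
  i <- 1L
  word_start <- NA_integer_
  flush_word <- function(end) {
    if (!is.na(word_start)) {
      toks[[length(toks) + 1L]] <<- list(
        type = "word",
        value = substr(text, word_start, end),
        pos = word_start
      )
      word_start <<- NA_integer_
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("'", "\"")) {
      flush_word(i - 1L)
      j <- i + 1L
      while (j <= n && chars[j] != ch) j <- j + 1L
      if (j > n) {
        stop(sprintf("rule parse error: unbalanced quote opened at position %d", i),
             call. = FALSE)
      }
      toks[[length(toks) + 1L]] <- list(
        type = "quoted",
        value = substr(text, i + 1L, j - 1L),
        pos = i
      )
      i <- j + 1L
    } else if (ch == "(" || ch == ")") {
      flush_word(i - 1L)
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else if (grepl("^\\s$", ch)) {
      flush_word(i - 1L)
      i <- i + 1L
    } else {
      if (is.na(word_start)) word_start <- i
      i <- i + 1L
    }
  }
  flush_word(n)
  toks
}

## ---- Parser ---------------------------------------------------------------

#' Parse a boolean keyword filter rule
#'
#' Parses the query language used for event filtering: adjacency is AND, a
#' standalone uppercase `OR` separates alternatives, parentheses group, and
#' quoted spans are exact phrases. A multi-word unquoted OR alternative is
#' interpreted as a phrase (see package rules documentation).
#'
#' @param rule_text A single character string, e.g.
#'   `"Boston (explosion OR terrorist)"`.
#' @return A filter-rule AST of class `mce_rule` with node kinds
#'   `term`, `phrase`, `and`, `or`.
#' @examples
#' parse_rule("Bomb (Boston OR marathon OR finish line)")
#' parse_rule("'Sandy Hook'")
#' @export
parse_rule <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) {
    stop("rule parse error: empty rule", call. = FALSE)
  }
  toks <- rule_lex(rule_text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  node <- parse_expr(state, depth = 0L)
  if (state$i <= length(toks)) {
    t <- toks[[state$i]]
    stop(sprintf("rule parse error: unbalanced ')' at position %d", t$pos),
         call. = FALSE)
  }
  node
}

peek_tok <- function(state) {
  if (state$i > length(state$toks)) NULL else state$toks[[state$i]]
}

## One operand parsed from a bare word: one token -> TERM, several (e.g.
## "6.0" -> [6, 0]) -> PHRASE, none -> error.
word_operand <- function(word, pos) {
  toks <- tokenize(word)
  if (length(toks) == 0L) {
    stop(sprintf("rule parse error: operand '%s' at position %d has no tokens",
                 word, pos), call. = FALSE)
  }
  if (length(toks) == 1L) rule_term(toks) else rule_phrase(toks)
}

parse_expr <- function(state, depth) {
  alternatives <- list()
  items <- list()      # operand nodes of the current alternative
  bare_words <- list() # raw words if every item so far is a bare word, else NULL
  close_alt <- function() {
    if (length(items) == 0L) {
      stop("rule parse error: empty OR alternative", call. = FALSE)
    }
    alternatives[[length(alternatives) + 1L]] <<- list(items = items, bare = bare_words)
    items <<- list()
    bare_words <<- list()
  }
  repeat {
    t <- peek_tok(state)
    if (is.null(t)) break
    if (t$type == ")") {
      if (depth == 0L) {
        stop(sprintf("rule parse error: unbalanced ')' at position %d", t$pos),
             call. = FALSE)
      }
      break
    }
    state$i <- state$i + 1L
    if (t$type == "word" && identical(t$value, "OR")) {
      close_alt()
    } else if (t$type == "word") {
      items[[length(items) + 1L]] <- word_operand(t$value, t$pos)
      if (!is.null(bare_words)) bare_words[[length(bare_words) + 1L]] <- t$value
    } else if (t$type == "quoted") {
      toks <- tokenize(t$value)
      if (length(toks) == 0L) {
        stop(sprintf("rule parse error: empty quoted phrase at position %d", t$pos),
             call. = FALSE)
      }
      items[[length(items) + 1L]] <- rule_phrase(toks)
      bare_words <- NULL
    } else if (t$type == "(") {
      child <- parse_expr(state, depth + 1L)
      nxt <- peek_tok(state)
      if (is.null(nxt) || nxt$type != ")") {
        stop(sprintf("rule parse error: unbalanced '(' at position %d", t$pos),
             call. = FALSE)
      }
      state$i <- state$i + 1L
      items[[length(items) + 1L]] <- child
      bare_words <- NULL
    }
  }
  close_alt()
  in_or <- length(alternatives) > 1L
  nodes <- lapply(alternatives, function(alt) {
    if (in_or && !is.null(alt$bare) && length(alt$items) >= 2L) {
      # unquoted multi-word OR alternative -> phrase
      rule_phrase(tokenize(paste(unlist(alt$bare), collapse = " ")))
    } else if (length(alt$items) == 1L) {
      alt$items[[1L]]
    } else {
      rule_and(alt$items)
    }
  })
  if (in_or) rule_or(nodes) else nodes[[1L]]
}

#' Render a filter rule back to query-language text
#'
#' Inverse of [parse_rule()]: `parse_rule(render_rule(r))` reproduces `r`
#' node-for-node. Phrases render quoted; non-leaf children are parenthesized.
#'
#' @param rule An `mce_rule` AST.
#' @return A single character string.
#' @export
render_rule <- function(rule) {
  stopifnot(inherits(rule, "mce_rule"))
  render_node <- function(node, parenthesize) {
    txt <- switch(node$kind,
      term = node$token,
      phrase = paste0("'", paste(node$tokens, collapse = " "), "'"),
      and = paste(vapply(node$children, render_node, "", parenthesize = TRUE),
                  collapse = " "),
      or = paste(vapply(node$children, render_node, "", parenthesize = TRUE),
                 collapse = " OR "),
      stop("unknown rule node kind: ", node$kind)
    )
    if (parenthesize && node$kind %in% c("and", "or")) paste0("(", txt, ")") else txt
  }
  render_node(rule, parenthesize = FALSE)
}

## ---- Evaluator ------------------------------------------------------------

phrase_at <- function(phrase, tokens) {
  k <- length(phrase)
  n <- length(tokens)
  if (k > n) return(FALSE)
  if (k == 1L) return(phrase %in% tokens)
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts <= n - k + 1L]
  for (s in starts) {
    if (all(tokens[s:(s + k - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

eval_rule_tokens <- function(node, tokens) {
  switch(node$kind,
    term = node$token %in% tokens,
    phrase = phrase_at(node$tokens, tokens),
    and = {
      for (ch in node$children) if (!eval_rule_tokens(ch, tokens)) return(FALSE)
      TRUE
    },
    or = {
      for (ch in node$children) if (eval_rule_tokens(ch, tokens)) return(TRUE)
      FALSE
    },
    stop("unknown rule node kind: ", node$kind)
  )
}

#' Test whether a text matches a filter rule
#'
#' @param rule An `mce_rule` AST from [parse_rule()].
#' @param text A single character string (matched case-insensitively on its
#'   token sequence).
#' @return `TRUE` or `FALSE`.
#' @examples
#' r <- parse_rule("Boston (explosion OR terrorist)")
#' matches(r, "Explosion in Boston")
#' @export
matches <- function(rule, text) {
  stopifnot(inherits(rule, "mce_rule"))
  eval_rule_tokens(rule, tokenize(text))
}

#' Test whether a text matches any rule in a list
#'
#' Events with several listed text patterns include a tweet when it matches
#' either (or both) pattern, i.e. the disjunction over rules. An empty rule
#' list matches nothing.
#'
#' @param rules List of `mce_rule` ASTs.
#' @param text A single character string.
#' @return `TRUE` or `FALSE`.
#' @export
matches_any <- function(rules, text) {
  tokens <- tokenize(text)
  for (r in rules) {
    stopifnot(inherits(r, "mce_rule"))
    if (eval_rule_tokens(r, tokens)) return(TRUE)
  }
  FALSE
}

## Vectorized disjunction over a character vector of texts; used by the
## pipeline so per-text tokenization happens once.
matches_any_many <- function(rules, texts) {
  toklist <- tokenize_all(texts)
  vapply(toklist, function(tk) {
    for (r in rules) if (eval_rule_tokens(r, tk)) return(TRUE)
    FALSE
  }, logical(1L))
}

## ---- Joint event+location keyword matching --------------------------------

#' Construct event/location keyword sets for joint matching
#'
#' Each operand string is tokenized: single-token operands become terms,
#' multi-token operands exact phrases.
#'
#' @param event_terms,location_terms Non-empty character vectors of keyword
#'   operands.
#' @return An object of class `mce_keyword_sets`.
#' @export
keyword_sets <- function(event_terms, location_terms) {
  stopifnot(is.character(event_terms), length(event_terms) >= 1L,
            is.character(location_terms), length(location_terms) >= 1L)
  parse_operands <- function(x) lapply(x, function(w) word_operand(w, 1L))
  structure(
    list(event = parse_operands(event_terms),
         location = parse_operands(location_terms)),
    class = "mce_keyword_sets"
  )
}

#' @export
print.mce_keyword_sets <- function(x, ...) {
  cat(sprintf("<keyword sets> %d event operands, %d location operands\n",
              length(x$event), length(x$location)))
  invisible(x)
}

#' Joint event-and-location keyword match
#'
#' The prospective surveillance filter: a text matches when it contains at
#' least one event-vocabulary operand AND at least one location-vocabulary
#' operand.
#'
#' @param keywords An `mce_keyword_sets` object.
#' @param text A single character string.
#' @return `TRUE` or `FALSE`.
#' @export
joint_match <- function(keywords, text) {
  stopifnot(inherits(keywords, "mce_keyword_sets"))
  tokens <- tokenize(text)
  any_operand <- function(ops) {
    for (op in ops) if (eval_rule_tokens(op, tokens)) return(TRUE)
    FALSE
  }
  any_operand(keywords$event) && any_operand(keywords$location)
}

## Vectorized joint match. When every operand is a single term (the common
## case for prospective keyword lists) this runs as flat set membership.
joint_match_many <- function(keywords, texts) {
  stopifnot(inherits(keywords, "mce_keyword_sets"))
  toklist <- tokenize_all(texts)
  all_terms <- function(ops) all(vapply(ops, function(o) o$kind == "term", TRUE))
  if (all_terms(keywords$event) && all_terms(keywords$location)) {
    ev <- vapply(keywords$event, `[[`, "", "token")
    lc <- vapply(keywords$location, `[[`, "", "token")
    idx <- rep.int(seq_along(toklist), lengths(toklist))
    u <- unlist(toklist, use.names = FALSE)
    hit <- function(set) {
      h <- logical(length(toklist))
      w <- idx[u %in% set]
      h[unique(w)] <- TRUE
      h
    }
    return(hit(ev) & hit(lc))
  }
  vapply(toklist, function(tk) {
    any(vapply(keywords$event, eval_rule_tokens, TRUE, tokens = tk)) &&
      any(vapply(keywords$location, eval_rule_tokens, TRUE, tokens = tk))
  }, logical(1L))
}

## ---- Rule files and packaged rule sets ------------------------------------

#' Read filter rules from a plain-text file
#'
#' One rule per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to a rule file.
#' @return A list of `mce_rule` ASTs.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_rule)
}

#' Packaged historical event filter rules
#'
#' The disaster-specific search rules for the five historical U.S.
#' mass-casualty case studies (2012--2014), keyed by event code:
#' `sh` (elementary-school shooting), `bb` (marathon bombing), `sf`
#' (airliner crash), `ne` (earthquake), `mv` (high-school shooting).
#'
#' @param event Optional event code; when omitted, all rule sets are
#'   returned as a named list.
#' @return A list of `mce_rule` (one event) or a named list of such lists.
#' @export
event_rules <- function(event = NULL) {
  path <- system.file("extdata", "event_rules.txt", package = "mcesignal",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  codes <- vapply(parts, `[[`, "", 1L)
  rules <- lapply(parts, function(p) parse_rule(p[[2L]]))
  out <- split(rules, factor(codes, levels = unique(codes)))
  if (is.null(event)) return(out)
  if (!event %in% names(out)) {
    stop("unknown event code: ", event, " (have: ",
         paste(names(out), collapse = ", "), ")", call. = FALSE)
  }
  out[[event]]
}

#' Packaged prospective event/location keyword sets
#'
#' The generic event and location keyword vocabularies used for the
#' prospective high-volume control experiment (a major sporting event in the
#' same metropolitan area).
#'
#' @return An `mce_keyword_sets` object.
#' @export
prospective_keywords <- function() {
  read_words <- function(fname) {
    path <- system.file("extdata", fname, package = "mcesignal", mustWork = TRUE)
    words <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
    words[nzchar(words) & !startsWith(words, "#")]
  }
  keyword_sets(read_words("sb50_event_keywords.txt"),
               read_words("sb50_location_keywords.txt"))
}
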