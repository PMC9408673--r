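# epiwatch corpus format (JSON Lines, UTF-8)

One JSON record per line. Messages and publishers share one file,
discriminated by `"record"`; the link graph is a separate JSON Lines
file of page records. Unknown fields are preserved on read but
ignored.

## Publisher record

```json
{"record": "publisher", "publisher_id": "pub001", "name_is_real": true,
 "platform_tier": 3, "history_count": 120, "false_history_prob": 0}
```

- `platform_tier`: 1 (primary), 2 (intermediate) or 3 (advanced).
- `history_count`: number of messages the account has published, >= 0.
- `false_history_prob`: regulatory state in [0, 1]; 0 for unseen
  publishers (optional, defaults to 0).

## Message record

```json
{"record": "message", "message_id": "m1", "publisher_id": "pub001",
 "timestamp": "2020-02-04",
 "clauses": [
   {"tokens": [["virus", "noun"], ["spreads", "verb"]],
    "polarity": "negative"}
 ],
 "raw_char_count": 100, "effective_char_count": 80,
 "places": ["wuhan"], "label": "true_info"}
```

- `timestamp`: ISO calendar date; the warning stage windows by day.
- `clauses[].tokens`: ordered `[token, pos]` pairs; `pos` is one of
  `noun`, `verb`, `adjective`, `adverb`, `other`.
- `clauses[].polarity`: `positive`, `negative` or `neutral` (one label
  per clause).
- `effective_char_count` <= `raw_char_count`.
- `label`: optional; `true_info` or `false_info`.
- Every `publisher_id` must resolve to a publisher record in the file.

## Link-graph page record (separate file)

```json
{"page_id": 1, "url": "https://example.org/1", "out_links": [2, 3],
 "text": ""}
```

- `page_id`: unique integer >= 1. Self-links and duplicate out-links
  are dropped on read.

## Auxiliary plain-text inputs

- Subject feature words / sentiment lexicon: one term per line.
- Gazetteer: CSV with header `place,province`.
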