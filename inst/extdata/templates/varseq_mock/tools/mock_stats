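#!/bin/sh
# toy read statistics: line and character counts of a reads file
IN=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_stats -i in -o out" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_stats: no such file: $IN" >&2; exit 1; }
lines=$(wc -l < "$IN" | tr -d ' ')
chars=$(wc -c < "$IN" | tr -d ' ')
printf 'metric\tvalue\nlines\t%s\nchars\t%s\n' "$lines" "$chars" > "$OUT"
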