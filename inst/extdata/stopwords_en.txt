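# Fixed English stopword list used by tokenize_posts(); one term per line.
# Versioned with the package so preprocessing is reproducible.
a
about
above
after
again
against
all
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
did
do
does
doing
down
during
each
few
for
from
further
get
got
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
if
in
into
is
it
its
itself
just
like
me
more
most
my
myself
no
nor
not
now
of
off
on
once
only
or
other
our
ours
ourselves
out
over
own
really
same
she
should
so
some
such
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
very
was
we
were
what
when
where
which
while
who
whom
why
will
with
would
you
your
yours
yourself
yourselves
also
always
among
anyone
anything
around
back
come
comes
even
ever
every
everyone
everything
first
going
gonna
im
ive
dont
didnt
doesnt
cant
wont
isnt
arent
wasnt
werent
hasnt
havent
couldnt
shouldnt
wouldnt
youre
youve
theyre
thats
whats
let
lets
many
may
maybe
much
must
never
next
one
onto
per
put
quite
rather
said
say
says
see
seen
shall
since
still
take
taken
tell
though
thus
told
upon
us
via
want
wants
way
well
went
without
yet
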