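# stop list used for global n-gram / bag-of-words features only; window
# features retain stop words. Deliberately excludes negation vocabulary.
a
an
the
of
in
on
at
by
with
for
to
from
and
or
but
is
are
was
were
be
been
being
this
that
these
those
it
its
as
which
who
whom
whose
we
our
they
their
he
she
have
has
had
do
does
did
may
might
can
could
would
should
will
such
than
then
there
here
when
where
while
also
between
among
upon
into
during
through
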